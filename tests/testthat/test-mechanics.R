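# Pairwise forces, spheroid contact, membrane elasticity, adhesion springs
# and the overdamped integrator.

test_that("pair force follows the piecewise repulsion/adhesion-well form", {
  # zero at rest separation and at the cutoff (continuity)
  expect_equal(pair_force(c(0, 0, 0), c(10, 0, 0), 10, 1, 1, 13),
               c(0, 0, 0))
  expect_equal(pair_force(c(13, 0, 0), c(0, 0, 0), 10, 1, 1, 13),
               c(0, 0, 0))
  expect_lt(max(abs(pair_force(c(12.999, 0, 0), c(0, 0, 0), 10, 1, 1, 13))),
            1e-3)
  # r = r_eq/2, k_rep = 1: repulsion of magnitude r_eq/2 pointing away from j
  f <- pair_force(c(5, 0, 0), c(0, 0, 0), 10, 1, 1, 13)
  expect_equal(f, c(5, 0, 0))
  # attraction peaks at the well midpoint with magnitude k_adh/4
  fm <- pair_force(c(11.5, 0, 0), c(0, 0, 0), 10, 1, 2, 13)
  expect_equal(fm[1], -2 / 4)
  expect_error(pair_force(c(1, 1, 1), c(1, 1, 1), 10, 1, 1, 13),
               "coincident")
})

test_that("effective separation rescales only the vertical component", {
  # spheres: plain Euclidean distance
  expect_equal(effective_separation(3, 4, 12, 5, 5, 5, 5), 13)
  # flat cells (c/a = 1/4) stacked vertically: 4x the centre distance
  expect_equal(effective_separation(0, 0, 2, 8, 2, 8, 2), 8)
  # same cells side by side: the lateral distance
  expect_equal(effective_separation(7, 0, 0, 8, 2, 8, 2), 7)
})

test_that("membrane stretching follows the spring law", {
  mesh <- list(pos = rbind(c(0, 0, 0), c(12, 0, 0)),
               edges = matrix(c(1L, 2L), 1), l0 = 10,
               hinges = matrix(integer(0), 0, 4))
  el <- membrane_elastic_forces(mesh, k_stretch = 3, k_bend = 1,
                                Lx = 100, Ly = 100)
  expect_equal(el$force[1, ], c(3 * 2, 0, 0))   # restoring k_stretch * delta
  expect_equal(el$force[2, ], c(-3 * 2, 0, 0))  # pulled back toward particle 1
  expect_equal(el$energy, 0.5 * 3 * 4)
})

test_that("a single hinge folded to 90 degrees stores E_bend = k_bend", {
  mesh <- list(pos = rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
                           c(0.5, 0, -1)),
               edges = matrix(integer(0), 0, 2), l0 = numeric(0),
               hinges = matrix(c(1L, 2L, 3L, 4L), 1))
  el <- membrane_elastic_forces(mesh, k_stretch = 1, k_bend = 2.5,
                                Lx = 100, Ly = 100)
  expect_equal(el$energy, 2.5)  # k_bend * (1 - cos 90)
})

test_that("bending forces equal the numerical energy gradient", {
  set.seed(3)
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0.2), c(0.4, -0.9, -0.3))
  mesh <- list(pos = pos, edges = matrix(integer(0), 0, 2), l0 = numeric(0),
               hinges = matrix(c(1L, 2L, 3L, 4L), 1))
  en <- function(p) {
    m <- mesh; m$pos <- p
    membrane_elastic_forces(m, 1, 1.7, 100, 100)$energy
  }
  el <- membrane_elastic_forces(mesh, 1, 1.7, 100, 100)
  h <- 1e-6
  for (i in 1:4) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    expect_equal(el$force[i, k], -(en(pp) - en(pm)) / (2 * h),
                 tolerance = 1e-5)
  }
  # degenerate triangle errors
  bad <- mesh; bad$pos[3, ] <- c(0.5, 0, 0)
  expect_error(membrane_elastic_forces(bad, 1, 1, 100, 100), "degenerate")
})

test_that("adhesion spring is zero at contact and scales with k", {
  st <- build_initial_state(tiny_params())
  mem <- st$mem$pos
  on_surface <- c(mem[1, 1], mem[1, 2], mem[1, 3] + 5)  # d = R exactly
  r0 <- adhesion_to_membrane(on_surface, mem, k = 15, R = 5, Lx = 60, Ly = 60)
  expect_equal(r0$force, c(0, 0, 0))
  lifted <- c(mem[1, 1], mem[1, 2], mem[1, 3] + 8)
  fs <- adhesion_to_membrane(lifted, mem, k = 15, R = 5, Lx = 60, Ly = 60)
  ft <- adhesion_to_membrane(lifted, mem, k = 3, R = 5, Lx = 60, Ly = 60)
  expect_equal(sqrt(sum(fs$force^2)) / sqrt(sum(ft$force^2)), 15 / 3)
  expect_equal(fs$force[3], -15 * 3)  # pulled straight down
})

test_that("vectorised cell forces match the naive double-loop oracle", {
  p <- tiny_params()
  set.seed(7)
  for (n in c(12, 50)) {
    pos <- cbind(runif(n, 0, p$Lx), runif(n, 0, p$Ly), runif(n, 0, 30))
    w <- runif(n, 0, p$w2)
    sh <- cell_shape(w, p$w2, p$R, p$q_min)
    st <- cells_only_state(pos, sh$a, sh$c, p)
    got <- compute_forces(st)$f_cell
    want <- oracle_cell_forces(pos, sh$a, sh$c, p)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("internal forces obey Newton's third law (momentum bookkeeping)", {
  st <- build_initial_state(tiny_params())
  st$derm$mobile[] <- TRUE  # include the otherwise-anchored bottom layer
  # perturb so every interaction class is active
  set.seed(11)
  st$cells$pos[, 3] <- st$cells$pos[, 3] + runif(length(st$cells$id), -1, 1)
  st$mem$pos[, 3] <- st$mem$pos[, 3] + runif(nrow(st$mem$pos), -0.5, 0.5)
  f <- compute_forces(st)
  tot <- colSums(f$f_derm) + colSums(f$f_mem) + colSums(f$f_cell)
  fmax <- max(abs(f$f_derm), abs(f$f_mem), abs(f$f_cell))
  expect_lt(max(abs(tot)), 1e-10 * max(fmax, 1))
})

test_that("pure mechanical relaxation descends the energy", {
  st <- build_initial_state(tiny_params(seed = 5L))
  set.seed(5)
  st$cells$pos <- st$cells$pos + cbind(runif(length(st$cells$id), -1, 1),
                                       runif(length(st$cells$id), -1, 1),
                                       runif(length(st$cells$id), 0, 2))
  e_prev <- total_energy(st)
  for (k in 1:20) {
    for (s in 1:10) step_state(st, st$params$dt)
    e <- total_energy(st)
    expect_lte(e, e_prev + 1e-8 * abs(e_prev))
    e_prev <- e
  }
})

test_that("a compressed pair relaxes to rest separation like the 1-D ODE", {
  p <- tiny_params()
  st <- cells_only_state(rbind(c(20, 30, 10), c(26, 30, 10)), params = p)
  # fine-step reference for the two-body gap r' = 2 k_rep (r_eq - r)
  r_ref <- 6
  dt_f <- p$dt / 50
  for (s in seq_len(round(0.5 / dt_f)))
    r_ref <- r_ref + dt_f * 2 * p$k_rep * max(10 - r_ref, 0)
  gaps <- numeric(0)
  for (s in seq_len(round(0.5 / p$dt))) {
    step_state(st, p$dt)
    gaps <- c(gaps, abs(st$cells$pos[2, 1] - st$cells$pos[1, 1]))
  }
  expect_true(all(diff(gaps) >= -1e-12))           # monotone approach
  expect_equal(gaps[length(gaps)], r_ref, tolerance = 0.01)
  expect_lt(abs(gaps[length(gaps)] - 10), 0.05)    # near rest separation
})

test_that("a pair at rest separation does not move and dt is bounded", {
  p <- tiny_params()
  st <- cells_only_state(rbind(c(20, 30, 10), c(30, 30, 10)), params = p)
  before <- st$cells$pos
  step_state(st, p$dt)
  expect_equal(st$cells$pos, before, tolerance = 1e-14)
  expect_error(step_state(st, 1), "stability")
})
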