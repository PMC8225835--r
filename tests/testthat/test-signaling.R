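# Field dynamics on the neighbour graph, cornification calcium release,
# lipids and desquamation.

test_that("graph diffusion conserves mass and decays isolated cells", {
  # pure decay on an isolated cell matches exp(-lambda t) within Euler error
  v <- 1
  pairs <- matrix(integer(0), 0, 2)
  for (s in 1:100) v <- graph_diffusion_step(v, pairs, dt = 0.01, D = 1,
                                             lambda = 2)
  expect_equal(v, exp(-2), tolerance = 0.03)  # explicit-Euler bias
  # lambda = 0: total mass conserved to 1e-10
  set.seed(21)
  v <- runif(20)
  pairs <- cbind(sample(20, 40, TRUE), sample(20, 40, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  tot <- sum(v)
  for (s in 1:50) v <- graph_diffusion_step(v, pairs, dt = 0.005, D = 1,
                                            lambda = 0)
  expect_equal(sum(v), tot, tolerance = 1e-10)
  expect_true(all(v >= 0))
})

test_that("two-cell exchange converges to the common mean", {
  # closed form: difference decays as exp(-2 D t)
  v <- c(1, 0)
  pairs <- matrix(c(1L, 2L), 1)
  t <- 0; dt <- 0.002
  for (s in 1:1000) { v <- graph_diffusion_step(v, pairs, dt, D = 1,
                                                lambda = 0); t <- t + dt }
  expect_equal(v[1] - v[2], exp(-2 * t), tolerance = 1e-2)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_equal(v, c(0.5, 0.5), tolerance = 0.1)
  expect_error(graph_diffusion_step(c(1, 0), pairs, dt = 2, D = 1,
                                    lambda = 0), "stability")
})

test_that("cornification dose is split equally and conserved", {
  st <- build_initial_state(tiny_params())
  st$cells$Ca[] <- 0
  # cell 1 cornifies with living suprabasal neighbours 2..5
  pairs <- cbind(c(1L, 3L, 1L, 1L), c(2L, 1L, 4L, 5L))  # either orientation
  st$cells$type[1] <- 5L
  st$cells$type[2:5] <- c(3L, 4L, 3L, 2L)  # any living neighbour qualifies
  cornification_release(st, 1L, pairs)
  Q <- st$params$Q_Ca
  expect_equal(st$cells$Ca[2:5], rep(Q / 4, 4))
  expect_equal(sum(st$cells$Ca), Q, tolerance = 1e-12)
  # two simultaneous cornifications are additive
  st$cells$Ca[] <- 0
  st$cells$type[1:2] <- 5L
  st$cells$type[3] <- 4L
  pairs2 <- cbind(c(1L, 2L), c(3L, 3L))
  cornification_release(st, 1:2, pairs2)
  expect_equal(st$cells$Ca[3], 2 * Q)
  # no living neighbour: dose discarded, total unchanged, warning logged
  st$cells$Ca[] <- 0
  before <- st$events$discarded_doses
  expect_warning(cornification_release(st, 1L, matrix(integer(0), 0, 2)),
                 "discarded")
  expect_equal(sum(st$cells$Ca), 0)
  expect_identical(st$events$discarded_doses, before + 1L)
})

test_that("lipids accumulate in granular cells only and transfer one-shot", {
  type <- c(3L, 4L, 5L)          # spinous, granular, cornified
  up <- lipid_update(type, Ca = c(0, 0, 0), L_in = c(0, 0, 0),
                     L_out = c(0, 0, 0), dt = 2, p_lip = 0.3, L_max = 1,
                     Ca_threshold = 0.05)
  expect_equal(up$L_in, c(0, 0.6, 0))     # p_lip * t, granular only
  expect_equal(up$L_out, c(0, 0, 0))
  # calcium above threshold releases the entire internal store
  up2 <- lipid_update(type, Ca = c(0, 0.1, 0), L_in = up$L_in,
                      L_out = up$L_out, dt = 0, p_lip = 0.3, L_max = 1,
                      Ca_threshold = 0.05)
  expect_equal(up2$L_out[2], 0.6)
  expect_equal(up2$L_in[2], 0)
  # cap: L_in + L_out never exceeds L_max
  up3 <- lipid_update(4L, Ca = 0, L_in = 0.3, L_out = 0.5, dt = 10,
                      p_lip = 0.3, L_max = 1, Ca_threshold = 0.05)
  expect_equal(up3$L_in + up3$L_out, 1)
})

test_that("desquamation needs both decayed junctions and surface exposure", {
  st <- build_initial_state(tiny_params())
  epidermsim:::remove_and_append(st, 3:length(st$cells$id))
  cl <- st$cells
  cl$type <- c(5L, 5L)
  cl$attached <- c(FALSE, FALSE)
  cl$pos <- rbind(c(30, 30, 20), c(30, 30, 26))  # stacked column
  cl$t_corn <- c(0, 0)
  cl$D <- c(0.5, 0.5)
  st$cells <- cl
  p <- st$params
  # D decays strictly monotonically
  desquamation_update(st, dt = 0.01)
  expect_lt(max(st$cells$D), 0.5)
  # drop D below threshold: only the exposed top cell is removed
  st$cells$D <- rep(p$D_th / 2, 2)
  desquamation_update(st, dt = 1e-9)
  expect_identical(length(st$cells$id), 1L)
  expect_equal(st$cells$pos[1, 3], 20)  # buried cell retained until exposed
  desquamation_update(st, dt = 1e-9)
  expect_identical(length(st$cells$id), 0L)
  ev <- event_log(st)
  expect_identical(nrow(ev$removals), 2L)
  expect_true(all(diff(ev$removals$time) >= 0))
})

test_that("calcium mass balance holds step by step", {
  p <- tiny_params(seed = 8L)
  st <- build_initial_state(p)
  run_simulation(st, 16, sample_every = 16)  # develop some cornifications
  audited <- 0L
  for (s in 1:120) {
    tot0 <- sum(st$cells$Ca)
    ids0 <- st$cells$id
    ev_n0 <- length(st$events$cornifications)
    disc0 <- st$events$discarded_doses
    nrem0 <- length(st$events$removals)
    suppressWarnings(step_simulation(st))
    if (length(st$events$removals) != nrem0) next  # removals carry Ca away
    n_corn <- if (length(st$events$cornifications) > ev_n0)
      sum(vapply(st$events$cornifications[(ev_n0 + 1):
                                            length(st$events$cornifications)],
                 nrow, integer(1))) else 0L
    injected <- p$Q_Ca * (n_corn - (st$events$discarded_doses - disc0))
    expected <- tot0 * (1 - p$dt * p$lambda_Ca) + injected
    expect_equal(sum(st$cells$Ca), expected,
                 tolerance = 1e-8)
    audited <- audited + 1L
  }
  expect_gt(audited, 80L)
})
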