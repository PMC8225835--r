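# Shared fixtures. Expensive simulation runs are computed once per test
# session and reused by several test files.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# small parameter set for fast mechanical tests
tiny_params <- function(...) {
  default_params(Lx = 60, Ly = 60, M1 = 2L, M2 = 2L, stem_spacing = 30,
                 ...)
}

# scaled-down homeostasis run shared by the acceptance anchors:
# fixture_small domain, 2-turnover burn-in plus >= 4 turnovers of
# measurement (28-day turnover scale).
fixture_homeostasis_run <- function() {
  memoise_fixture("fixture_homeostasis", function() {
    sc <- scenario_params("fixture_small", seed = 101, days = 170)
    res <- run_scenario(sc, sample_every = 0.5)
    res
  })
}

# naive O(n^2) force oracle over a plain cell system (no dermis/membrane):
# pairwise spheroid forces at the effective separation, periodic in x, y.
oracle_cell_forces <- function(pos, a, cc, p) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  mi <- function(d, L) d - L * round(d / L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- mi(pos[i, 1] - pos[j, 1], p$Lx)
    dy <- mi(pos[i, 2] - pos[j, 2], p$Ly)
    dz <- pos[i, 3] - pos[j, 3]
    s <- 0.5 * (a[i] / cc[i] + a[j] / cc[j])
    reff <- sqrt(dx^2 + dy^2 + (s * dz)^2)
    req <- a[i] + a[j]
    rc <- p$rcut_factor * req
    if (reff >= rc) next
    fs <- if (reff < req) p$k_rep * (req - reff) else
      -p$k_adh_cell * (reff - req) * (rc - reff) / (rc - req)^2
    f[i, ] <- f[i, ] + fs * c(dx, dy, s^2 * dz) / reff
  }
  f
}

# build a bare state holding only cells (single dermal/membrane particles
# pushed far away so they interact with nothing)
cells_only_state <- function(pos, a = NULL, cc = NULL, params = tiny_params()) {
  st <- build_initial_state(params)
  n <- nrow(pos)
  keep <- seq_len(n)
  cl <- st$cells
  for (f in names(cl)) {
    cl[[f]] <- if (f == "pos") pos else rep(cl[[f]][1], n)
  }
  cl$id <- seq_len(n)
  cl$lineage <- seq_len(n)
  if (!is.null(a)) cl$a <- a
  if (!is.null(cc)) cl$c <- cc
  cl$type <- rep(3L, n)        # detached spinous: no membrane spring
  cl$attached <- rep(FALSE, n)
  st$cells <- cl
  # park dermis and membrane far below so they cannot interact with cells
  st$derm$pos[, 3] <- st$derm$pos[, 3] - 500
  st$mem$pos[, 3] <- st$mem$pos[, 3] - 450
  st
}
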