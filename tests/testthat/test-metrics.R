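# Layer morphometrics (subregion grid), lipid/basal diagnostics, membrane
# amplitude and turnover statistics.

test_that("tile thickness is the sphere volume per tile area", {
  g <- subregion_grid(100, 100, 2, 2)
  # empty grid
  expect_equal(thickness_grid(numeric(0), numeric(0), g, 5),
               matrix(0, 2, 2))
  # 3 cells of radius 5 in one 50x50 tile: H = pi/5
  H <- thickness_grid(c(10, 20, 30), c(10, 10, 10), g, 5)
  expect_equal(H[1, 1], pi / 5)
  expect_equal(sum(H > 0), 1L)
  # linearity in the count
  H2 <- thickness_grid(rep(c(10, 20, 30), 2), rep(10, 6), g, 5)
  expect_equal(H2[1, 1], 2 * H[1, 1])
})

test_that("tile dispersion is the z-range minus the thickness", {
  g <- subregion_grid(100, 100, 2, 2)
  H <- thickness_grid(c(10, 20, 30), c(10, 12, 14), g, 5)
  G <- dispersion_grid(c(10, 20, 30), c(10, 12, 14), c(10, 12, 14), g, H)
  expect_equal(G[1, 1], 4 - pi / 5)
  expect_true(all(is.na(G[-1])))  # empty tiles undefined
  # single cell: G = -H (z_max = z_min)
  H1 <- thickness_grid(10, 10, g, 5)
  G1 <- dispersion_grid(10, 10, 33, g, H1)
  expect_equal(G1[1, 1], -H1[1, 1])
  # translation in z leaves G unchanged
  G3 <- dispersion_grid(c(10, 20, 30), c(10, 12, 14),
                        c(10, 12, 14) + 7.3, g, H)
  expect_equal(G3[1, 1], G[1, 1])
})

test_that("layer means and spatial variation follow their definitions", {
  H <- matrix(c(1, 3, 1, 3), 2, 2)
  G <- matrix(c(2, 2, NA, 2), 2, 2)
  m <- layer_means(H, G)
  expect_equal(m$H, 2)
  expect_equal(m$G, 2)          # NA tiles excluded
  expect_equal(spatial_variation(H), 1)  # population sd of {1,3}
  expect_equal(spatial_variation(matrix(4, 3, 3)), 0)
  # invariant under tile relabeling
  expect_equal(spatial_variation(matrix(sample(as.vector(H)), 2, 2)),
               spatial_variation(H))
})

test_that("metric grids match naive double-loop oracles on random snapshots", {
  set.seed(13)
  for (rep in 1:3) {
    g <- subregion_grid(120, 90, 4, 3)
    n <- 200
    x <- runif(n, 0, 120); y <- runif(n, 0, 90); z <- runif(n, 0, 60)
    H <- thickness_grid(x, y, g, 5)
    G <- dispersion_grid(x, y, z, g, H)
    # oracle: explicit loops over tiles and cells
    for (i in 1:4) for (j in 1:3) {
      inij <- x >= (i - 1) * 30 & x < i * 30 & y >= (j - 1) * 30 & y < j * 30
      expect_equal(H[i, j], 4 * pi * 125 * sum(inij) / (3 * 30 * 30),
                   tolerance = 1e-12)
      if (any(inij))
        expect_equal(G[i, j], max(z[inij]) - min(z[inij]) - H[i, j],
                     tolerance = 1e-12)
    }
    expect_equal(layer_means(H, G)$H, mean(H), tolerance = 1e-12)
    expect_equal(spatial_variation(H), sqrt(mean((H - mean(H))^2)),
                 tolerance = 1e-12)
  }
})

test_that("lipid statistics use the strict 50% convention", {
  expect_equal(lipid_stats(c(1, 1, 1), 1), list(ratio = 1, n_deficient = 0L))
  expect_equal(lipid_stats(c(1.0, 0.4), 1),
               list(ratio = 0.7, n_deficient = 1L))
  expect_equal(lipid_stats(0.5, 1)$n_deficient, 0L)  # exactly 50%: kept
  expect_true(is.na(lipid_stats(numeric(0), 1)$ratio))
})

test_that("basal statistics count events, attachment and budget", {
  bs <- basal_stats(div_times = seq(0.25, 10, by = 0.25),
                    attached = c(TRUE, TRUE, FALSE),
                    div_left = c(Inf, 0, 3), window = 10, t_now = 10)
  expect_equal(bs$div_per_day, 4)
  expect_identical(bs$n_basal, 2L)
  expect_identical(bs$n_proliferative, 1L)  # stem counts, exhausted TA not
  expect_error(basal_stats(1, TRUE, 1, window = 0, t_now = 1), "window")
})

test_that("membrane amplitude is the vertical max-min range", {
  m <- cbind(runif(30), runif(30), rep(2.5, 30))
  expect_equal(membrane_amplitude(m), 0)
  m[7, 3] <- 5.5
  expect_equal(membrane_amplitude(m), 3)
})

test_that("turnover statistics recompute from the raw removal log", {
  rem <- data.frame(time = 28, id = 1, t_birth = 0, t_corn = 14,
                    born_div = 1, lineage = 1, abnormal = 0)
  ts <- turnover_stats(rem)
  expect_equal(ts$turnover, 28)
  expect_equal(ts$corn_lag, 14)
  # random log vs brute-force recomputation
  set.seed(31)
  n <- 50
  rem2 <- data.frame(time = runif(n, 20, 60), id = seq_len(n),
                     t_birth = runif(n, 0, 10),
                     t_corn = c(runif(n - 5, 10, 20), rep(NA, 5)),
                     born_div = rbinom(n, 1, 0.8), lineage = 1,
                     abnormal = 0)
  ts2 <- turnover_stats(rem2, from = 25, to = 55)
  sel <- rem2$time >= 25 & rem2$time <= 55
  expect_equal(ts2$turnover,
               mean((rem2$time - rem2$t_birth)[sel & rem2$born_div == 1]))
  expect_equal(ts2$corn_lag,
               mean((rem2$time - rem2$t_corn)[sel & !is.na(rem2$t_corn)]))
})
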