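# Division scheduling, stem/TA rules, delamination, differentiation,
# type assignment and flattening.

test_that("division scheduling is lognormal around T_div", {
  # deterministic limit
  expect_equal(schedule_division_time(10, 4, cycle_cv = 0, abnormal = FALSE),
               14)
  # abnormal lineage divides twice as fast
  expect_equal(schedule_division_time(10, 4, cycle_cv = 0, abnormal = TRUE),
               12)
  # Monte Carlo mean within 1% of T_div at cv = 0.2
  set.seed(99)
  draws <- schedule_division_time(0, 4, cycle_cv = 0.2,
                                  abnormal = rep(FALSE, 1e4))
  expect_equal(mean(draws), 4, tolerance = 0.01)
  expect_equal(sd(draws) / mean(draws), 0.2, tolerance = 0.05)
})

test_that("TA division budget is exhausted after N_div rounds (2^N_div cells)", {
  st <- build_initial_state(tiny_params(N_div = 2L))
  # keep a single fresh TA cell
  ta <- which(st$cells$type == 2L)[1]
  drop <- setdiff(seq_along(st$cells$id), ta)
  epidermsim:::remove_and_append(st, drop)
  rounds <- 0L
  repeat {
    due <- which(st$cells$attached & st$cells$type == 2L &
                   st$cells$div_left > 0)
    if (!length(due)) break
    divide_cells(st, due)
    rounds <- rounds + 1L
    expect_lt(rounds, 10L)
  }
  expect_identical(length(st$cells$id), 4L)        # 2^N_div descendants
  expect_true(all(st$cells$div_left == 0))
  expect_identical(rounds, 2L)
})

test_that("stem division is asymmetric: stem count conserved, TA added", {
  st <- build_initial_state(tiny_params())
  n_stem <- sum(st$cells$type == 1L)
  n0 <- length(st$cells$id)
  for (k in 1:3) {
    stems <- which(st$cells$type == 1L)
    divide_cells(st, stems)
    expect_identical(sum(st$cells$type == 1L), n_stem)
  }
  new_ta <- length(st$cells$id) - n0
  expect_identical(new_ta, 3L * n_stem)
  # fresh TA daughters carry the full division budget
  expect_true(all(st$cells$div_left[st$cells$type == 2L &
                                      st$cells$born_div] ==
                    st$params$N_div))
  expect_error(divide_cells(st, which(!st$cells$attached)[1]),
               "not attached and proliferative")
})

test_that("delamination turns detached TA into spinous and is TA-only", {
  st <- build_initial_state(tiny_params())
  ta <- which(st$cells$type == 2L)[1:3]
  delaminate_cells(st, ta)
  expect_true(all(st$cells$type[ta] == 3L))
  expect_true(all(!st$cells$attached[ta]))
  expect_true(all(st$cells$w[ta] == 0))
  # a detached TA with remaining budget still differentiates: budget is
  # irrelevant once the membrane bond is lost
  expect_true(all(st$cells$div_left[ta] > 0))
  expect_true(all(is.infinite(st$cells$next_div[ta])))
  stem <- which(st$cells$type == 1L)[1]
  expect_error(delaminate_cells(st, stem), "only TA")
})

test_that("differentiation speed is linear in calcium and stimulant", {
  expect_equal(advance_differentiation(0, 0, 0, dt = 1, alpha = 0.1,
                                       beta_Ca = 2, beta_S = 1), 0.1)
  # beta_Ca * Ca = 1 doubles the rate
  expect_equal(advance_differentiation(0, 0.5, 0, dt = 1, alpha = 0.1,
                                       beta_Ca = 2, beta_S = 1), 0.2)
  # abnormal lineage differentiates twice as fast
  expect_equal(advance_differentiation(0, 0, 0, dt = 1, alpha = 0.1,
                                       beta_Ca = 2, beta_S = 1,
                                       abnormal = TRUE), 0.2)
  expect_error(advance_differentiation(-1, 0, 0, 1, 0.1, 1, 1), "negative")
})

test_that("type thresholds are half-open and ordered", {
  expect_identical(assign_type(0, 1, 2), 3L)                 # spinous
  expect_identical(assign_type(1, 1, 2), 4L)                 # w = w1: granular
  expect_identical(assign_type(2, 1, 2), 5L)                 # w = w2: cornified
  expect_identical(assign_type(c(0.99, 1.99, 5), 1, 2), c(3L, 4L, 5L))
})

test_that("flattening conserves volume and reaches the terminal ratio", {
  p <- default_params()
  s0 <- cell_shape(0, p$w2, p$R, p$q_min)
  expect_equal(s0$a, p$R)
  expect_equal(s0$c, p$R)
  w <- seq(0, 2 * p$w2, length.out = 41)
  sh <- cell_shape(w, p$w2, p$R, p$q_min)
  expect_lt(max(abs(sh$a^2 * sh$c - p$R^3)), 1e-12)
  # aspect ratio decreases monotonically to q_min and stays there
  q <- sh$c / sh$a
  expect_true(all(diff(q) <= 1e-12))
  expect_equal(q[w >= p$w2], rep(p$q_min, sum(w >= p$w2)))
  sf <- cell_shape(p$w2, p$w2, p$R, 0.25)
  expect_equal(sf$a, p$R * 4^(1 / 3))
  expect_equal(sf$c, sf$a / 4)
})
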