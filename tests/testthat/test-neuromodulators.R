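test_that("the network dopamine signal is the value prediction error", {
  w <- msn_weights(1, 1, init = 0)
  expect_equal(compute_delta(w, 1, 1, reward = 1), 1)
  w$w_d1[1, 1] <- 0.5
  expect_equal(compute_delta(w, 1, 1, reward = 0.5), 0)
  expect_equal(compute_delta(w, 1, 1, reward = -1), -1.5)
})

test_that("the PD clamp caps positive dopamine and medication adds a
           fixed increment", {
  off <- pd_condition("pd_off", delta_lim = 0.001)
  on <- pd_condition("pd_on", delta_lim = 0.001, delta_med = 0.021)
  expect_equal(apply_pd(0.5, off), 0.001)
  expect_equal(apply_pd(0.5, on), 0.022)
  expect_equal(apply_pd(-0.2, off), -0.2)          # below ceiling
  expect_equal(apply_pd(0.5, pd_condition("control")), 0.5)
})

test_that("the clamp is monotone, bounded and the control map is the
           identity", {
  grid <- seq(-2, 2, by = 0.05)
  ctrl <- pd_condition("control")
  off <- pd_condition("pd_off", delta_lim = 0.001)
  on <- pd_condition("pd_on", delta_lim = 0.001, delta_med = 0.021)
  expect_identical(apply_pd(grid, ctrl), grid)
  for (cond in list(off, on)) {
    y <- apply_pd(grid, cond)
    expect_true(all(diff(y) >= 0))
    ceiling <- cond$delta_lim +
      if (cond$status == "pd_on") cond$delta_med else 0
    expect_true(all(y <= ceiling + 1e-12))
  }
})

test_that("presets carry the published serotonin and clamp values", {
  ctrl <- pd_preset("controls")
  expect_equal(ctrl$serotonin$alpha_d1d2, 0.2)
  off <- pd_preset("pd_off")
  expect_equal(off$serotonin$alpha_d2, 0.99)
  expect_equal(off$pd$delta_lim, 0.001)
  on <- pd_preset("pd_on")
  expect_equal(on$pd$delta_med, 0.021)
  expect_equal(on$serotonin$alpha_d2, 0.2)
  expect_error(serotonin_params(-0.1, 1, 1))
})

test_that("a near-zero clamp cripples positive-surprise learning while
           punishments pass through", {
  # train one reward pair and one punishment pair of the classification
  # task with forced balanced sampling under the never-medicated clamp
  task <- classification_task()
  gs <- gain_preset("table8")
  eta <- c(d1 = 0.01, d2 = 0.1, d1d2 = 0.1)
  off <- pd_condition("pd_off", delta_lim = 0.001)
  set.seed(21)
  w <- msn_weights(4, 2, eta = eta, init = 0.5)
  init <- w$w_d1
  for (k in 1:40) {
    for (s in c(1L, 3L)) {
      for (a in 1:2) {
        r <- sample_classification_outcome(task, s, a)
        d <- apply_pd(compute_delta(w, s, a, r), off)
        w <- update_weights(w, gs, s, a, d)
      }
    }
  }
  drift <- abs(w$w_d1 - init)
  # the punished response of the punishment image moves far more than
  # the rewarded response of the reward image ever can under the clamp
  expect_gt(drift[3, 2], 3 * drift[1, 1])
  # and the reward pair cannot rise above initialization
  expect_lt(w$w_d1[1, 1], init[1, 1] + 0.05)
})
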