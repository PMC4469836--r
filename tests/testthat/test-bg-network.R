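gpi <- gain_preset("table3")

make_weights <- function(y_d1, y_d2 = c(0, 0), y_d1d2 = c(0, 0)) {
  w <- msn_weights(1, 2, init = 0)
  w$w_d1[1, ] <- y_d1; w$w_d2[1, ] <- y_d2; w$w_d1d2[1, ] <- y_d1d2
  w
}

test_that("direct-pathway contribution scales value by the gated gain", {
  w <- make_weights(c(0.5, 0.2))
  expect_equal(dp_contribution(w, gpi, alpha_d1 = 0, du = 1, state = 1),
               c(0, 0))
  # the table3 D1 gain is a bipolar sigmoid centred at -0.01
  expect_equal(dp_contribution(w, gpi, 1, du = -0.01, 1), c(0, 0))
  expect_equal(dp_contribution(w, gpi, 1, du = 100, 1), c(0.5, 0.2),
               tolerance = 1e-6)
})

test_that("indirect-pathway contribution combines D2 and signed risk
           terms", {
  w <- make_weights(c(0.5, -0.5), y_d2 = c(0.3, 0.3), y_d1d2 = c(1, 1))
  expect_equal(ip_contribution(w, gpi, 0, 0, du = 0.3, 1), c(0, 0))
  # with symmetric D2 and risk magnitudes, flipping the value sign flips
  # only the risk component
  x <- ip_contribution(w, gpi, alpha_d2 = 1, alpha_d1d2 = 1, du = 0, 1)
  d2_part <- evaluate_gain(gpi$d2, 0) * 0.3
  risk_part <- d1d2_gain(gpi, 0) * 1
  expect_equal(x, c(d2_part + risk_part, d2_part - risk_part))
  # ablation removes the dependence on the sign of y_d1
  x_ab <- ip_contribution(w, gpi, 1, 1, du = 0, 1, sign_term = FALSE)
  expect_equal(x_ab[1], x_ab[2])
})

test_that("STN-GPe stepping preserves fixed points, bounds and
           dimensions", {
  np <- network_params()
  st <- bg_dynamics_state(2, network_params(init_scale = 0))
  expect_equal(st$x_stn, c(0, 0))
  st2 <- step_stn_gpe(st, x_ip = c(0, 0), np)
  expect_equal(st2$x_stn, c(0, 0))            # all-zero fixed point
  expect_equal(st2$x_gpe, c(0, 0))
  expect_error(step_stn_gpe(st, x_ip = c(0, 0, 0), np), "channels")

  set.seed(1)
  st <- bg_dynamics_state(2, np)
  for (k in 1:500) {
    st <- step_stn_gpe(st, c(0, 0), np)
    expect_true(all(abs(st$y_stn) <= 1))
    expect_true(all(abs(c(st$x_stn, st$x_gpe)) < 10))
  }
  # the coupled loop does not settle: activity stays non-constant
  st2 <- step_stn_gpe(st, c(0, 0), np)
  expect_false(isTRUE(all.equal(st$x_stn, st2$x_stn)))
})

test_that("GPi combines pathways and thalamic afferents negate GPi", {
  np <- network_params()
  expect_equal(gpi_combine(c(1, 0), c(0, 0), np), c(-1, 0))
  expect_equal(gpi_combine(c(0, 0), c(0.3, -0.3), np), c(0.3, -0.3))
  expect_equal(gpi_combine(c(1, 1), c(0.5, 0.5),
                           network_params(w_stn_gpi = 0)), c(-1, -1))
  set.seed(2)
  res <- select_action(c(0.4, -0.1), c(0.1, 0), np)
  expect_equal(res$state$x_thal, -res$state$x_gpi)
})

test_that("selection is reproducible and symmetric inputs give
           equiprobable actions", {
  np <- network_params()
  set.seed(3)
  a1 <- replicate(50, select_action(c(0.2, 0.1), c(0, 0), np)$action)
  set.seed(3)
  a2 <- replicate(50, select_action(c(0.2, 0.1), c(0, 0), np)$action)
  expect_identical(a1, a2)

  set.seed(4)
  draws <- replicate(10000, select_action(c(0, 0), c(0, 0), np)$action)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)
})

test_that("without striatal drive a three-channel network explores
           approximately uniformly", {
  w <- msn_weights(1, 3, init = 0.5)
  sero <- serotonin_params(0, 0, 0)
  np <- network_params()
  set.seed(5)
  draws <- replicate(6000, {
    thalamus_select(w, gpi, sero, du = 0.5, state = 1, params = np)$action
  })
  for (a in 1:3) expect_lt(abs(mean(draws == a) - 1 / 3), 0.05)
})

test_that("a dominant value channel under rising utility is exploited", {
  w <- make_weights(c(3, 0.1))
  sero <- serotonin_params(1, 0, 0)
  np <- network_params()
  set.seed(6)
  draws <- replicate(1000, {
    thalamus_select(w, gpi, sero, du = 1, state = 1, params = np)$action
  })
  expect_gt(mean(draws == 1), 0.95)
})

test_that("silencing the STN leaves selection to the direct pathway", {
  np <- network_params(silence_stn = TRUE)
  set.seed(7)
  draws <- replicate(50, select_action(c(1, 0), c(0.4, 0), np)$action)
  expect_true(all(draws == 1))
})

test_that("non-finite drives are rejected with a diagnostic", {
  set.seed(8)
  expect_error(select_action(c(NaN, 0), c(0, 0)), "non-finite")
})
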