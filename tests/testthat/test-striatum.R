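test_that("MSN responses read back the one-hot weight entries", {
  set.seed(1)
  w <- msn_weights(3, 2)
  w$w_d1[2, 1] <- 0.7
  y <- msn_response(w, 2, 1)
  expect_equal(y[["d1"]], 0.7)
  expect_equal(y[["d2"]], w$w_d2[2, 1])
  expect_equal(y[["d1d2"]], w$w_d1d2[2, 1])
  expect_error(msn_response(w, 4, 1), "unknown")
})

test_that("weight initialization uses the current RNG stream in [0, 1]", {
  set.seed(9)
  w1 <- msn_weights(4, 2)
  set.seed(9)
  w2 <- msn_weights(4, 2)
  expect_identical(w1$w_d1, w2$w_d1)
  expect_true(all(w1$w_d1 >= 0 & w1$w_d1 <= 1))
  w3 <- msn_weights(2, 2, init = 0)
  expect_true(all(w3$w_d1d2 == 0))
})

test_that("updates touch only the visited entry of each pool", {
  set.seed(2)
  gs <- gain_preset("table1")
  w <- msn_weights(3, 2)
  w2 <- update_weights(w, gs, 2, 2, delta = 0.8)
  changed <- sum(w2$w_d1 != w$w_d1) + sum(w2$w_d2 != w$w_d2) +
    sum(w2$w_d1d2 != w$w_d1d2)
  expect_lte(changed, 3)
  # table1 has no D2 column: the D2 pool is untouched
  expect_identical(w2$w_d2, w$w_d2)
  # the bipolar D1 gain is zero at its midpoint, so delta = 0 is inert
  w3 <- update_weights(w, gs, 1, 1, delta = 0)
  expect_equal(w3$w_d1, w$w_d1)
  # forced arithmetic: eta * gain
  w4 <- msn_weights(1, 1, eta = c(d1 = 0.1, d2 = 0.1, d1d2 = 0.1),
                    init = 0)
  hd <- gain_set(d1 = gain_params(1, -5, 0, "tangent_sigmoid"),
                 hd1 = gain_params(0.05, -1, 0, "log_sigmoid"),
                 hd2 = gain_params(0.05, 1, 0, "log_sigmoid"))
  w4 <- update_weights(w4, hd, 1, 1, delta = 0)
  expect_equal(w4$w_d1d2[1, 1], 0.1 * 0.05)   # 0.1 * (0.025 + 0.025)
})

test_that("network utility matches the risk-adjusted value read-out", {
  w <- msn_weights(1, 1, init = 0)
  w$w_d1[1, 1] <- 0.4; w$w_d1d2[1, 1] <- 0.1
  expect_equal(network_utility(w, 0.2, 1, 1), 0.38)
  expect_equal(network_utility(w, 0, 1, 1), 0.4)
  w$w_d1[1, 1] <- -0.4
  expect_equal(network_utility(w, 1, 1, 1), -0.3)
  # ablating the sign term applies the risk penalty on both sides
  expect_equal(network_utility(w, 1, 1, 1, sign_term = FALSE), -0.5)
})

test_that("utility gradient has a zero first-trial convention", {
  expect_equal(delta_u(0.5, 0.2), 0.3)
  expect_equal(delta_u(0.4, 0.4), 0)
  expect_equal(delta_u(0.9, NULL), 0)
})

test_that("linear-gain D1 learning is bit-identical to abstract
           Q-learning on a shared reward stream", {
  lin <- gain_set(d1 = gain_params(1, 0, 0, "linear"),
                  d2 = gain_params(1, 0, 0, "linear"),
                  hd1 = gain_params(0.5, 0, 0, "linear"),
                  hd2 = gain_params(0.5, 0, 0, "linear"))
  set.seed(11)
  rewards <- rnorm(200)
  w <- msn_weights(1, 1, eta = c(d1 = 0.1, d2 = 0.1, d1d2 = 0.1),
                   init = 0)
  ag <- abstract_agent(1, 1, eta_q = 0.1)
  w_traj <- q_traj <- numeric(200)
  for (t in seq_along(rewards)) {
    d_net <- compute_delta(w, 1, 1, rewards[[t]])
    w <- update_weights(w, lin, 1, 1, d_net)
    d_abs <- td_error(ag, 1, 1, rewards[[t]])
    ag <- update_value(ag, 1, 1, d_abs)
    w_traj[t] <- w$w_d1[1, 1]; q_traj[t] <- ag$Q[1, 1]
  }
  expect_identical(w_traj, q_traj)
})

test_that("complementary D1 weights satisfy both coupling identities
           after every update", {
  set.seed(3)
  w <- msn_weights(2, 2, complementary = TRUE)
  gs <- gain_preset("table6")
  for (k in 1:50) {
    s <- sample(1:2, 1); a <- sample(1:2, 1)
    w <- update_weights(w, gs, s, a, delta = rnorm(1))
    expect_identical(w$w_d1[1, 1], -w$w_d1[1, 2])
    expect_identical(w$w_d1[1, 1], -w$w_d1[2, 1])
    expect_identical(w$w_d1[1, 1], w$w_d1[2, 2])
  }
  expect_error(msn_weights(3, 2, complementary = TRUE), "2 x 2")
})

test_that("the co-expressing pool tracks the shape of the Bernoulli
           variance across reward probabilities", {
  demo <- risk_tracking_demo(p_values = seq(0.1, 0.9, by = 0.2),
                             n_trials = 1500, seed = 4)
  # peak at p = 0.5, vanishing toward the deterministic extremes
  expect_equal(demo$p[which.max(demo$y_d1d2)], 0.5)
  expect_gt(min(demo$y_d1d2[demo$p == 0.5]),
            max(demo$y_d1d2[demo$p %in% c(0.1, 0.9)]))
  expect_gt(cor(demo$y_d1d2, demo$variance, method = "spearman"), 0.8)
  # the abstract estimator recovers the variance itself
  expect_true(all(abs(demo$h_abstract - demo$variance) < 0.05))
  # the D1 read-out is ordered with the reward probability (its
  # saturating gain places the fixed point near the median, not the mean)
  expect_true(all(diff(demo$y_d1) > 0))
})
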