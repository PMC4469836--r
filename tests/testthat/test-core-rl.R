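test_that("TD error follows the single- and multi-step definitions", {
  ag <- abstract_agent(2, 2, gamma = 0.9)
  expect_equal(td_error(ag, 1, 1, reward = 1), 1)          # zero-value base
  ag$Q[2, 2] <- 1
  expect_equal(td_error(ag, 1, 1, reward = 0, next_state = 2,
                        next_action = 2, mode = "multi_step"), 0.9)
  ag$Q[1, 1] <- 0.7
  expect_equal(td_error(ag, 1, 1, reward = 0.7), 0)        # fixed point
  expect_error(td_error(ag, 3, 1, reward = 0), "unknown")
  expect_error(td_error(ag, 1, 1, reward = 0, mode = "multi_step"),
               "next_state")
})

test_that("value updates are local and approach the mean exponentially", {
  ag <- abstract_agent(2, 2, eta_q = 0.5)
  ag2 <- update_value(ag, 1, 1, delta = 1)
  expect_equal(ag2$Q[1, 1], 0.5)
  expect_equal(ag2$Q[-1], ag$Q[-1])                        # other entries
  expect_equal(update_value(ag, 1, 1, delta = 0)$Q, ag$Q)  # fixed point

  # constant reward 1, eta 0.1: Q_t = 1 - (1 - eta)^t in closed form
  ag <- abstract_agent(1, 1, eta_q = 0.1)
  for (t in 1:100) {
    ag <- update_value(ag, 1, 1, td_error(ag, 1, 1, reward = 1))
  }
  expect_equal(ag$Q[1, 1], 1 - 0.9^100, tolerance = 1e-12)
  expect_lt(abs(ag$Q[1, 1] - 1), 1e-3)
})

test_that("risk prediction error and update follow their definitions", {
  ag <- abstract_agent(1, 1, eta_h = 0.1)
  expect_equal(risk_prediction_error(ag, 1, 1, delta = 1), 1)
  ag$h[1, 1] <- 0.25
  expect_equal(risk_prediction_error(ag, 1, 1, delta = 0), -0.25)
  ag$h[1, 1] <- 0.49
  expect_equal(risk_prediction_error(ag, 1, 1, delta = 0.7), 0)
  ag$h[1, 1] <- 0
  expect_equal(update_risk(ag, 1, 1, xi = 1)$h[1, 1], 0.1)
})

test_that("risk estimate converges to the Bernoulli variance", {
  # with the value held at the mean, h tracks E[delta^2] = p(1-p)
  set.seed(1)
  rewards <- as.numeric(runif(10000) < 0.5)
  ag <- abstract_agent(1, 1, eta_q = 0.01, eta_h = 0.01, q_init = 0.5)
  for (r in rewards) {
    d <- td_error(ag, 1, 1, r)
    ag <- update_risk(ag, 1, 1, risk_prediction_error(ag, 1, 1, d))
  }
  expect_lt(abs(ag$h[1, 1] - 0.25), 0.05)

  # joint value + risk learning at p = 0.9
  set.seed(2)
  ag <- abstract_agent(1, 1, eta_q = 0.01, eta_h = 0.01)
  ag <- train_iid(ag, as.numeric(runif(10000) < 0.9))
  expect_lt(abs(ag$h[1, 1] - 0.09), 0.05)
})

test_that("value estimate converges to the reward mean", {
  # E[Q] reaches the mean; the time-average over the stationary phase
  # estimates it without the O(sqrt(eta)) single-sample wobble
  for (mu in c(-1, 0, 0.5, 1)) {
    set.seed(100 + round(10 * mu))
    rewards <- rnorm(10000, mean = mu, sd = 0.5)
    ag <- abstract_agent(1, 1, eta_q = 0.01, eta_h = 0.01)
    q_traj <- numeric(length(rewards))
    for (t in seq_along(rewards)) {
      ag <- update_value(ag, 1, 1, td_error(ag, 1, 1, rewards[[t]]))
      q_traj[t] <- ag$Q[1, 1]
    }
    expect_lt(abs(mean(q_traj[2001:10000]) - mu), 0.05)
  }
})

test_that("utility is risk averse for gains and risk seeking for losses", {
  expect_equal(utility(0.5, 0.2, 1), 0.3)
  expect_equal(utility(-0.5, 0.2, 1), -0.3)
  expect_equal(utility(0, 0.7, 1), 0)            # sign(0) = 0
  expect_equal(utility(c(0.5, -2), c(9, 9), 0), c(0.5, -2))  # alpha = 0
})

test_that("softmax policy normalizes, flattens at beta 0, sharpens at
           large beta, and is monotone in utility", {
  p <- softmax_probs(c(3, -1, 0.4), beta = 2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(softmax_probs(c(5, -3), beta = 0), c(0.5, 0.5))
  expect_equal(softmax_probs(c(7, 7), beta = 3), c(0.5, 0.5))
  expect_gt(softmax_probs(c(1, 0), beta = 100)[1], 0.999)
  # raising one utility raises its probability
  p_lo <- softmax_probs(c(0.2, 0.8), beta = 1)[1]
  p_hi <- softmax_probs(c(0.6, 0.8), beta = 1)[1]
  expect_gt(p_hi, p_lo)
  # overflow safety
  expect_equal(sum(softmax_probs(c(1e4, 0), beta = 1)), 1)
  expect_error(softmax_policy(numeric(0), beta = 1), "empty")
})

test_that("softmax sampling is reproducible and matches its probabilities", {
  set.seed(5)
  a1 <- softmax_policy(c(0.5, 0.1, -0.2), beta = 2)
  set.seed(5)
  a2 <- softmax_policy(c(0.5, 0.1, -0.2), beta = 2)
  expect_identical(a1, a2)
  set.seed(6)
  draws <- replicate(4000, softmax_policy(c(1, 0), beta = 1)$action)
  expect_equal(mean(draws == 1), softmax_probs(c(1, 0), 1)[1],
               tolerance = 0.03)
})

test_that("agent tables serialize to a tidy data frame", {
  ag <- abstract_agent(2, 3)
  ag$Q[2, 3] <- 0.7
  df <- as.data.frame(ag)
  expect_equal(nrow(df), 6)
  expect_equal(df$Q[df$state == 2 & df$action == 3], 0.7)
  expect_named(df, c("state", "action", "Q", "h"))
})
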