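test_that("the risk schedule validates its equal-expected-value states", {
  sched <- risk_schedule()
  expect_equal(nrow(sched), 6)
  eev <- sched[sched$group == "eev", ]
  expect_equal((eev$risky1 + eev$risky2) / 2, eev$safe)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(state = 1, safe = 100, risky1 = 10, risky2 = 20,
                       group = "eev"), bad, row.names = FALSE)
  expect_error(risk_schedule(bad), "EEV")
})

test_that("risk outcomes are base-subtracted and split half-half", {
  sched <- risk_schedule()
  expect_equal(sample_risk_outcome(sched, 1, "safe"), 150 - 159.83)
  expect_equal(sample_risk_outcome(risk_schedule(reward_base = 150),
                                   1, "safe"), 0)
  set.seed(31)
  draws <- sample_risk_outcome(sched, 2, "risky", n = 100000)
  expect_lt(abs(mean(draws) - (150 - 159.83)), 0.5)   # law of large numbers
  expect_lt(abs(mean(draws + 159.83 == 100) - 0.5), 0.01)
})

test_that("classification outcomes respect the published probabilities
           and valences", {
  task <- classification_task()
  set.seed(32)
  # optimal responses receive the good outcome at rate 0.8
  good_reward <- sample_classification_outcome(task, 1, 1, n = 100000)
  expect_lt(abs(mean(good_reward == 1) - 0.8), 0.01)
  expect_true(all(good_reward >= 0))                  # rewards never punish
  good_punish <- sample_classification_outcome(task, 3, 1, n = 100000)
  expect_lt(abs(mean(good_punish == 0) - 0.8), 0.01)
  expect_true(all(good_punish <= 0))                  # punishers never pay
  bad_punish <- sample_classification_outcome(task, 4, 1, n = 50000)
  expect_lt(abs(mean(bad_punish == -1) - 0.8), 0.015)
})

test_that("an always-correct oracle policy makes no errors and ends
           stages at their criteria", {
  set.seed(33)
  ag <- bg_agent(2, 2, gain_preset("table6"),
                 eta = c(d1 = 0.01, d2 = 0.01, d1d2 = 0.01),
                 complementary = TRUE)
  res <- run_reversal_block(ag, "unexpected_reward",
                            select_override = function(s, rewarding) {
                              if (s == rewarding) 1L else 2L
                            })
  expect_equal(sum(res$trials$error), 0)
  expect_equal(nrow(res$trials), 120)
  # every stage lasts exactly its drawn criterion of correct responses,
  # so the full reversal budget is consumed
  expect_equal(max(res$trials$stage), 16)
  stage_len <- table(res$trials$stage)
  expect_true(all(stage_len[as.character(0:15)] %in% 5:9))
})

test_that("the reversal harness emits exactly 4 x 120 trials per agent
           with complementary weights throughout", {
  res <- run_reversal_experiment(
    conditions = list(balanced = serotonin_params(1, 5, 1)),
    n_agents = 2, master_seed = 41, keep_trials = TRUE)
  counts <- table(res$trials$agent)
  expect_true(all(counts == 480))
  expect_true(all(res$trials$trial <= 120))
  expect_equal(sort(unique(res$trials$block)), 1:4)
  # two blocks of each condition
  bc <- unique(res$trials[, c("agent", "block", "block_condition")])
  expect_true(all(table(bc$agent, bc$block_condition) == 2))
  # summary shape: one row per statistic
  expect_setequal(res$summary$statistic,
                  c("errors_total", "errors_reward", "errors_punishment",
                    "errors_unexpected_reward",
                    "errors_unexpected_punishment"))
})

test_that("the classification harness emits exactly 160 balanced trials", {
  res <- run_pd_experiment(
    conditions = pd_conditions()["pd_on"],
    n_agents = 2, master_seed = 42, keep_trials = TRUE)
  counts <- table(res$trials$agent)
  expect_true(all(counts == 160))
  expect_true(all(table(res$trials$state, res$trials$agent) == 40))
})

test_that("experiment summaries are bit-reproducible under a master seed
           and respond to it", {
  r1 <- run_risk_experiment(n_agents = 3, trials_per_state = 5,
                            master_seed = 7)
  r2 <- run_risk_experiment(n_agents = 3, trials_per_state = 5,
                            master_seed = 7)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_risk_experiment(n_agents = 3, trials_per_state = 5,
                            master_seed = 8)
  expect_false(identical(r1$summary$mean, r3$summary$mean))
  expect_equal(unique(r1$summary$n), 3)
  # standard errors are sd over agents / sqrt(n)
  sub <- r1$per_agent[r1$per_agent$condition == "baseline", ]
  expect_equal(r1$summary$se[r1$summary$condition == "baseline" &
                               r1$summary$statistic == "safe_overall"],
               sd(sub$safe_overall) / sqrt(3))
})
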