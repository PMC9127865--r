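test_that("seeded simulation is bit-reproducible and structurally valid", {
  cfg <- fig5_config()
  d1 <- simulate_agent("OL1", c(beta = 0.1, alpha1 = 0.2), cfg, seed = 9)
  d2 <- simulate_agent("OL1", c(beta = 0.1, alpha1 = 0.2), cfg, seed = 9)
  expect_identical(d1, d2)
  expect_silent(validate_dataset(d1, config = cfg))
  n_learn <- sum(d1$phase == "learning")
  expect_true(n_learn >= 100 && n_learn <= 300)
  expect_true(all(d1$r_chosen[d1$phase == "learning"] >=
                    pmax(0, cfg$mu[d1$choice[d1$phase == "learning"]] - 3)))
})

test_that("cohorts validate across model families and regimes", {
  for (regime in c("partial", "complete")) {
    cfg <- task_config(regime = regime)
    for (model in c("SQL", "RPA", "Hyb", "FQL", "EWA", "SBE", "RelAsym",
                    "OL2", if (regime == "complete") "Dif")) {
      d <- simulate_cohort(model, 2, cfg, seed = 31)
      expect_silent(validate_dataset(d, config = cfg))
      meta <- attr(d, "meta")
      expect_identical(meta$s001$model, model)
    }
  }
})

test_that("exploitative agents with distinct values learn nearly perfectly", {
  # optimistic midpoint initialization avoids greedy lock-in, so a strongly
  # exploitative learner converges on the advantageous option
  cfg <- task_config(q0 = 50)
  d <- simulate_agent("SQL", c(beta = 0.9, alpha1 = 0.1), cfg, seed = 8)
  acc <- performance(d, "learning", cfg)$fraction
  expect_gt(acc, 0.85)
  d0 <- simulate_agent("SQL", c(beta = 0, alpha1 = 0.1), cfg, seed = 8)
  expect_equal(performance(d0, "learning", cfg)$fraction, 0.5,
               tolerance = 0.15)
})

test_that("parameter samplers respect bounds, constraints and feasibility", {
  mom <- default_param_moments("OL1", "partial")
  expect_equal(mom$mean[mom$param == "beta"], 0.02)
  expect_equal(mom$sd[mom$param == "alpha1"], 0.20)
  set.seed(2)
  draws <- param_sampler(mom)(500)
  expect_true(all(draws$beta > 0 & draws$beta < 1))
  expect_true(all(draws$alpha1 > 0 & draws$alpha1 < 1))
  expect_lt(abs(mean(draws$beta) - 0.02), 0.005)
  # OL2 coupling enforced by the sampler
  set.seed(3)
  d2 <- param_sampler(default_param_moments("OL2", "partial"),
                      model = "OL2")(500)
  expect_true(all(d2$alpha2 <= d2$alpha1))
  # infeasible moments are rejected with the offending parameter named
  bad <- data.frame(param = c("beta", "alpha1"), mean = c(0.1, 0.5),
                    sd = c(0.05, 0.9))
  expect_error(param_sampler(bad)(10), "alpha1")
  # empty and degenerate cohorts
  cfg <- task_config()
  expect_equal(nrow(simulate_cohort("OL1", 0, cfg, seed = 1)), 0)
  const <- function(n) data.frame(beta = rep(0.05, n), alpha1 = rep(0.3, n))
  dd <- simulate_cohort("OL1", 3, cfg, seed = 1, sampler = const)
  meta <- attr(dd, "meta")
  expect_true(all(vapply(meta, function(m) m$params$alpha1, 1) == 0.3))
})

test_that("value correlation follows the learning-rate ratio law at the endpoints", {
  r1 <- qvalue_correlation_experiment(0.2, 0.2, 0.1, seed = 11)
  expect_equal(r1$mean, -1, tolerance = 1e-8)   # antisymmetry is exact
  expect_equal(r1$law, -1)
  r0 <- qvalue_correlation_experiment(0.2, 0, 0.1, seed = 12)
  expect_lt(abs(r0$mean), 0.1)
  expect_equal(r0$law, 0)
  expect_length(r1$per_run, 20)
  expect_warning(qvalue_correlation_experiment(0.2, 0.2, 0.1, n_runs = 1,
                                               seed = 1), "standard error")
  # ensemble estimator variant
  re <- qvalue_correlation_experiment(0.2, 0.2, 0.1, seed = 13,
                                      estimator = "ensemble")
  expect_equal(re$mean, -1, tolerance = 1e-8)
})

test_that("performance grid: random at beta = 0, advantage grows with the rate ratio", {
  g0 <- run_performance_grid(betas = 0, ratios = c(0, 1), n_trials = 300,
                             n_reps = 60, seed = 21)
  expect_equal(g0$mean, c(0.5, 0.5), tolerance = 0.02)
  g1 <- run_performance_grid(ratios = c(0, 1), n_reps = 150, seed = 22)
  expect_gt(g1$mean[g1$ratio == 1], g1$mean[g1$ratio == 0])
  one <- run_performance_grid(pairs = list(c(8, 6)), ratios = 0.5,
                              n_reps = 1, seed = 23)
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$sd) || one$sd == 0)
})

test_that("hybrid-outcome opposing learning reduces to plain opposing learning on shifted means", {
  # complete-feedback OL with hybrid prediction error is distributionally an
  # OL learner whose option i pays N(mu_i - (1-w) mu_j, sigma')
  set.seed(77)
  w <- 0.5; mu <- c(7, 5); a <- 0.2; beta <- 0.1
  n <- 600; runs <- 40
  acc_ext <- replicate(runs, {
    st <- init_state()
    hits <- 0L
    for (t in 1:n) {
      p1 <- softmax_choice_prob(st$q["A1"], st$q["B"], beta)
      ch <- if (runif(1) < p1) "A1" else "B"
      un <- if (ch == "A1") "B" else "A1"
      rc <- rnorm(1, mu[1 + (ch == "B")], 1)
      ru <- rnorm(1, mu[1 + (un == "B")], 1)
      st <- ol_step(st, list(chosen = ch, unchosen = un, r_chosen = rc,
                             r_unchosen = ru),
                    c(beta = beta, alpha1 = a, w = w), "complete")
      hits <- hits + (ch == "A1")
    }
    hits / n
  })
  mu_eff <- c(mu[1] - (1 - w) * mu[2], mu[2] - (1 - w) * mu[1])
  sd_eff <- sqrt(1 + (1 - w)^2)
  acc_simple <- replicate(runs, {
    st <- init_state()
    hits <- 0L
    for (t in 1:n) {
      p1 <- softmax_choice_prob(st$q["A1"], st$q["B"], beta)
      ch <- if (runif(1) < p1) "A1" else "B"
      un <- if (ch == "A1") "B" else "A1"
      rc <- rnorm(1, mu_eff[1 + (ch == "B")], sd_eff)
      st <- ol_step(st, list(chosen = ch, unchosen = un, r_chosen = rc),
                    c(beta = beta, alpha1 = a), "partial")
      hits <- hits + (ch == "A1")
    }
    hits / n
  })
  se <- sqrt(var(acc_ext) / runs + var(acc_simple) / runs)
  expect_lt(abs(mean(acc_ext) - mean(acc_simple)), 3 * se + 0.01)
})
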