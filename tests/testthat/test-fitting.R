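cfg_p <- task_config()

test_that("information criteria follow the closed forms", {
  ic <- information_criteria(100 * log(2), k = 2, n = 100)
  expect_equal(unname(ic["bic"]), 200 * log(2) + 2 * log(100))
  expect_equal(unname(ic["aic"]), 200 * log(2) + 4)
  ic0 <- information_criteria(12.5, k = 0, n = 40)
  expect_equal(unname(ic0["bic"]), 25)
  expect_equal(unname(ic0["aic"]), 25)
  # ln n = 2 makes both penalties equal for any k
  ic2 <- information_criteria(10, k = 3, n = exp(2))
  expect_equal(unname(ic2["bic"]), unname(ic2["aic"]))
})

test_that("indifferent likelihoods are exactly T log 2", {
  d <- simulate_agent("OL1", c(beta = 0.05, alpha1 = 0.3), cfg_p, seed = 2)
  T_ans <- sum(d$phase == "learning" & !is.na(d$choice))
  for (m in c("SQL", "OL1", "FQL", "SBE")) {
    pm <- random_params(m, "partial"); pm["beta"] <- 0
    expect_equal(learning_nll(m, pm, d), T_ans * log(2), tolerance = 1e-12)
  }
  tn <- transfer_nll("OL1", c(beta = 0, alpha1 = 0.3), d)
  expect_equal(unname(tn["total"]), 24 * log(2), tolerance = 1e-12)
  expect_equal(unname(tn["a1a2"]), 4 * log(2), tolerance = 1e-12)
})

test_that("compiled and reference replays agree to machine precision", {
  set.seed(51)
  for (regime in c("partial", "complete")) {
    cfg <- task_config(regime = regime)
    for (m in names(model_registry(regime))) {
      pm <- random_params(m, regime)
      d <- simulate_agent(m, pm, cfg, seed = 60 + nchar(m))
      p2 <- random_params(m, regime)
      expect_equal(learning_nll(m, p2, d, engine = "cpp"),
                   learning_nll(m, p2, d, engine = "r"),
                   tolerance = 1e-12)
    }
  }
})

test_that("likelihood replay matches the brute-force oracle on random datasets", {
  set.seed(99)
  for (regime in c("partial", "complete")) {
    for (m in names(model_registry(regime))) {
      for (rep in 1:3) {
        tr <- random_trials(40, regime)
        pa <- random_params(m, regime)
        want <- oracle_nll(m, pa, tr, regime)
        d <- trials_to_dataset(tr, regime)
        got <- learning_nll(m, pa, d, regime = regime)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("MAP fitting is deterministic and its optimum beats every start", {
  d <- simulate_agent("OL1", c(beta = 0.08, alpha1 = 0.3), cfg_p, seed = 14)
  f1 <- map_fit("OL1", d, n_restarts = 1, seed = 5)
  f2 <- map_fit("OL1", d, n_restarts = 1, seed = 5)
  expect_identical(f1, f2)
  # the reported MAP objective is never above the objective at the start
  prior_pen <- function(th) -sum(dbeta(th, 1.2, 1.2, log = TRUE))
  set.seed(5)
  start <- rbeta(2, 1.2, 1.2)
  obj_start <- learning_nll("OL1", c(beta = start[1], alpha1 = start[2]), d) +
    prior_pen(start)
  expect_lte(f1$objective, obj_start + 1e-9)
  expect_gte(f1$nll, 0)
  expect_gte(f1$bic, 2 * f1$nll)
})

test_that("fitting rejects degenerate inputs", {
  d <- simulate_agent("OL1", c(beta = 0.08, alpha1 = 0.3), cfg_p, seed = 14)
  d$choice[d$phase == "learning"] <- NA
  expect_error(map_fit("OL1", d), "no answered learning trials")
  expect_error(learning_nll("OL1", c(beta = 2, alpha1 = 0.3),
                            simulate_agent("OL1", c(beta = 0.08,
                                                    alpha1 = 0.3),
                                           cfg_p, seed = 14)),
               "out of bounds")
  expect_error(map_fit("Dif", d, regime = "partial"), "not defined")
})

test_that("a nesting model never fits worse than its special case", {
  # flat prior turns the MAP objective into the pure likelihood
  set.seed(41)
  for (s in c(3, 4)) {
    d <- simulate_agent("Hyb", c(beta = 0.06, alpha1 = 0.35, w = 0.6),
                        cfg_p, seed = s)
    f_sql <- map_fit("SQL", d, n_restarts = 8, seed = 1,
                     prior_shape = c(1, 1))
    f_hyb <- map_fit("Hyb", d, n_restarts = 8, seed = 1,
                     prior_shape = c(1, 1))
    f_ol2 <- map_fit("OL2", d, n_restarts = 8, seed = 1,
                     prior_shape = c(1, 1))
    expect_lte(f_hyb$nll, f_sql$nll + 1e-6)   # SQL = Hyb at w = 1
    expect_lte(f_ol2$nll, f_sql$nll + 1e-6)   # SQL = OL2 at alpha2 = 0
  }
})

test_that("generating parameters score no worse than perturbed ones (median)", {
  # at this value scale the softmax saturates once the contrast is large,
  # so the informative perturbations are *underestimates* of the rates
  truth <- c(beta = 0.1, alpha1 = 0.3)
  for (wrong in list(c(beta = 0.1, alpha1 = 0.05),
                     c(beta = 0.02, alpha1 = 0.3))) {
    diffs <- vapply(1:50, function(s) {
      d <- simulate_agent("OL1", truth, cfg_p, seed = 200 + s)
      learning_nll("OL1", wrong, d) - learning_nll("OL1", truth, d)
    }, numeric(1))
    expect_gt(median(diffs), 0)
  }
})

test_that("the cohort fit object supports the standard methods", {
  d <- simulate_cohort("OL1", 4, cfg_p, seed = 77)
  f <- rl_fit(d, "OL1", n_restarts = 3, seed = 1)
  expect_s3_class(f, "rl_fit")
  expect_equal(nrow(f$fits), 4)
  expect_equal(dim(coef(f)), c(4, 2))
  ll <- logLik(f)
  expect_equal(as.numeric(ll), -sum(f$fits$learning_nll))
  expect_equal(attr(ll, "df"), 8)
  s <- summary(f)
  expect_s3_class(s, "summary.rl_fit")
  expect_output(print(s), "OL1")
  pr <- predict(f, phase = "transfer")
  expect_equal(nrow(pr), 4 * 24)
  expect_true(all(pr$p_choice > 0 & pr$p_choice <= 1))
  pn <- predict(f, phase = "transfer", type = "nll")
  expect_equal(sort(pn$nll), sort(f$fits$transfer_nll), tolerance = 1e-8)
  res <- residuals(f)
  expect_true(all(abs(res$residual) < 1))
  sim <- simulate(f, seed = 3)
  expect_silent(validate_dataset(sim, config = cfg_p))
  expect_identical(sort(unique(sim$subject)), sort(f$fits$subject))
})
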