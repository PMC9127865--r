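fb_p <- function(ch, un, r) list(chosen = ch, unchosen = un, r_chosen = r)
fb_c <- function(ch, un, r, ru)
  list(chosen = ch, unchosen = un, r_chosen = r, r_unchosen = ru)

test_that("softmax choice probability matches the logistic form", {
  expect_equal(softmax_choice_prob(10, 10, 0.3), 0.5)
  expect_equal(softmax_choice_prob(80, 3, 0), 0.5)
  expect_equal(softmax_choice_prob(15, 5, 0.1), 1 / (1 + exp(-1)))
  # complementarity and numerical stability at extreme arguments
  expect_equal(softmax_choice_prob(15, 5, 0.1) +
                 softmax_choice_prob(5, 15, 0.1), 1)
  expect_equal(softmax_choice_prob(1e4, 0, 5), 1)
  expect_gt(softmax_choice_prob(0, 100, 0.5), 0)
  # the log-probability path stays finite even where the probability
  # underflows double precision
  expect_true(is.finite(oppolearn:::.log_softmax_prob(0, 1e4, 5)))
})

test_that("hybrid reward mixes absolute and relative strategies", {
  expect_equal(hybrid_reward(64, 54, 1), 64)
  expect_equal(hybrid_reward(64, 54, 0), 10)
  expect_equal(hybrid_reward(64, 54, 0.5), 37)
  expect_error(hybrid_reward(64, 54, 1.5))
})

test_that("standard Q-learning updates only the chosen value", {
  st <- init_state(); st$q["A1"] <- 50; st$q["B"] <- 33
  out <- sql_step(st, fb_p("A1", "B", 64), c(beta = 0.1, alpha1 = 0.25))
  expect_equal(unname(out$q["A1"]), 53.5)
  expect_equal(unname(out$q["B"]), 33)
  full <- sql_step(st, fb_p("A1", "B", 64), c(beta = 0.1, alpha1 = 1))
  expect_equal(unname(full$q["A1"]), 64)
  none <- sql_step(st, fb_p("A1", "B", 64), c(beta = 0.1, alpha1 = 0))
  expect_equal(none$q, st$q)
  # extended form requires complete feedback and the counterfactual outcome
  expect_error(sql_step(st, fb_p("A1", "B", 64),
                        c(beta = 0.1, alpha1 = 0.3, alpha2 = 0.3),
                        regime = "partial", extended = TRUE))
  ext <- sql_step(st, fb_c("A1", "B", 64, 43),
                  c(beta = 0.1, alpha1 = 0.25, alpha2 = 0.5),
                  regime = "complete", extended = TRUE)
  expect_equal(unname(ext$q["B"]), 38)
})

test_that("reference-point model revalues outcomes against the context value", {
  p <- c(beta = 0.1, alpha1 = 1, alpha2 = 0.5)
  st <- init_state(); st$q["A1"] <- 20; st$q["B"] <- 44
  # RPA partial: contextual reward is the average of r_ch and Q_un
  out <- rp_step(st, fb_p("A1", "B", 64), p, "partial", "RPA")
  expect_equal(out$v[1], (64 + 44) / 2)  # alpha1 = 1 jumps V to r_x = 54
  expect_equal(unname(out$q["A1"]), 20 + 0.5 * ((64 - 54) - 20))
  # RPD: r_x is the chosen outcome itself; delta_ch uses the updated V
  out2 <- rp_step(init_state(), fb_p("A1", "B", 64), p, "partial", "RPD")
  expect_equal(out2$v[1], 64)
  expect_equal(unname(out2$q["A1"]), 0)   # (64 - 64) - 0 = 0
  # RPM complete: max of the two outcomes; unchosen updated at alpha3
  p3 <- c(p, alpha3 = 0.25)
  out3 <- rp_step(init_state(), fb_c("A1", "B", 50, 70), p3,
                  "complete", "RPM")
  expect_equal(out3$v[1], 70)
  expect_equal(unname(out3$q["A1"]), 0.5 * (50 - 70))
  expect_equal(unname(out3$q["B"]), 0.25 * (70 - 70))
  # other context untouched
  expect_equal(unname(out3$q[c("A2", "C")]), c(0, 0))
})

test_that("difference model learns the outcome difference (complete only)", {
  p <- c(beta = 0.1, alpha1 = 0.5)
  out <- dif_step(init_state(), fb_c("A1", "B", 64, 54), p)
  expect_equal(unname(out$q["A1"]), 5)
  expect_error(dif_step(init_state(), fb_p("A1", "B", 64), p,
                        regime = "partial"))
  st <- init_state(); st$q["A1"] <- 8
  same <- dif_step(st, fb_c("A1", "B", 60, 60), c(beta = 0.1, alpha1 = 0.5))
  expect_equal(unname(same$q["A1"]), 4)   # pulled toward 0
  full <- dif_step(init_state(), fb_c("A1", "B", 64, 54),
                   c(beta = 0.1, alpha1 = 1))
  expect_equal(unname(full$q["A1"]), 10)
})

test_that("hybrid model nests SQL (w = 1) and Dif (w = 0, complete)", {
  st <- init_state(); st$q["A1"] <- 12; st$q["B"] <- 7
  p <- function(w) c(beta = 0.1, alpha1 = 0.3, w = w)
  fb <- fb_c("A1", "B", 64, 54)
  expect_equal(hyb_step(st, fb, p(1), "complete")$q,
               sql_step(st, fb, c(beta = 0.1, alpha1 = 0.3), "complete")$q)
  expect_equal(hyb_step(st, fb, p(0), "complete")$q,
               dif_step(st, fb, c(beta = 0.1, alpha1 = 0.3), "complete")$q)
  half <- hyb_step(st, fb, p(0.5), "complete")
  expect_equal(unname(half$q["A1"]), 12 + 0.3 * (37 - 12))
  # partial feedback substitutes Q_un for the counterfactual outcome
  half_p <- hyb_step(st, fb_p("A1", "B", 64), p(0.5), "partial")
  rhyb <- 0.5 * 64 + 0.5 * (64 - 7)
  expect_equal(unname(half_p$q["A1"]), 12 + 0.3 * (rhyb - 12))
})

test_that("forgetting Q-learning decays the unchosen value", {
  st <- init_state(); st$q["B"] <- 40
  p <- c(beta = 0.1, alpha1 = 0.3, alpha2 = 0.9)
  out <- fql_step(st, fb_p("A1", "B", 64), p)
  expect_equal(unname(out$q["B"]), 36)
  keep <- fql_step(st, fb_p("A1", "B", 64),
                   c(beta = 0.1, alpha1 = 0.3, alpha2 = 1))
  expect_equal(unname(keep$q["B"]), 40)
  gone <- fql_step(st, fb_p("A1", "B", 64),
                   c(beta = 0.1, alpha1 = 0.3, alpha2 = 0))
  expect_equal(unname(gone$q["B"]), 0)
})

test_that("experience-weighted attraction tracks experience weights", {
  # rho = 0, phi = 0: one-shot replacement by the reward
  out <- ewa_step(init_state(), fb_p("A1", "B", 64),
                  c(beta = 0.1, phi = 0, rho = 0))
  expect_equal(unname(out$n["A1"]), 1)
  expect_equal(unname(out$q["A1"]), 64)
  # N = 1, rho = 1, phi = 1, Q = 50, r = 64 -> N = 2, Q = 57
  st <- init_state(); st$q["A1"] <- 50
  out2 <- ewa_step(st, fb_p("A1", "B", 64), c(beta = 0.1, phi = 1, rho = 1))
  expect_equal(unname(out2$n["A1"]), 2)
  expect_equal(unname(out2$q["A1"]), 57)
  # complete feedback, delta_imit = 0: unchosen value purely decays
  st$q["B"] <- 30
  out3 <- ewa_step(st, fb_c("A1", "B", 64, 54),
                   c(beta = 0.1, phi = 0.5, rho = 1, delta_imit = 0),
                   "complete")
  expect_equal(unname(out3$q["B"]), 30 * 1 * 0.5 / 2)
  expect_equal(unname(out3$n["B"]), 2)
})

test_that("sample-based episodic likelihood is a proper recency mixture", {
  # empty histories: pseudo-samples at q0 -> softmax of equal values
  expect_equal(sbe_trial_likelihood(numeric(0), integer(0), numeric(0),
                                    integer(0), 1, 0.5, 0.1), 0.5)
  # beta = 0: indifference regardless of history
  expect_equal(sbe_trial_likelihood(c(90, 10), c(1, 2), 50, 1, 3, 0.5, 0),
               0.5)
  # single sample: weight renormalizes to 1
  expect_equal(sbe_trial_likelihood(10, 1, numeric(0), integer(0), 2,
                                    0.5, 0.1),
               softmax_choice_prob(10, 0, 0.1))
  # raw recency weight alpha (1 - alpha)^(t - i): 0.25 for i = t - 1, a = .5
  p_raw <- sbe_trial_likelihood(10, 2, numeric(0), integer(0), 3, 0.5, 0.1,
                                normalize = FALSE)
  expect_equal(p_raw, 0.25 * softmax_choice_prob(10, 0, 0.1))
  # two-sample hand computation with normalized weights
  w <- c(0.5 * 0.5^2, 0.5 * 0.5^1); w <- w / sum(w)
  by_hand <- sum(w * softmax_choice_prob(c(20, 60), 35, 0.1))
  expect_equal(sbe_trial_likelihood(c(20, 60), c(1, 2), 35, 1, 3, 0.5, 0.1),
               by_hand)
  expect_error(sbe_trial_likelihood(10, 5, numeric(0), integer(0), 3,
                                    0.5, 0.1))
})

test_that("relative-asymmetric updating is confirmatory with flipped sign for unchosen", {
  p <- c(beta = 0.1, alpha1 = 0, alpha_conf = 0.3, alpha_disc = 0.1)
  # alpha1 = 0 freezes V at q0 = 0, so deltas are easy to stage
  st <- init_state(); st$q["A1"] <- 10; st$q["B"] <- 5
  # chosen: delta = (20 - 0) - 10 = +10 -> confirmatory rate
  out <- relasym_step(st, fb_c("A1", "B", 20, 1), p, "complete")
  expect_equal(unname(out$q["A1"]), 13)
  # unchosen: delta = (1 - 0) - 5 = -4 -> *confirmatory* branch (flipped)
  expect_equal(unname(out$q["B"]), 5 - 0.3 * 4)
  # disconfirmatory branches
  out2 <- relasym_step(st, fb_c("A1", "B", 4, 9), p, "complete")
  expect_equal(unname(out2$q["A1"]), 10 + 0.1 * (4 - 10))
  expect_equal(unname(out2$q["B"]), 5 + 0.1 * (9 - 5))
  # equal rates reduce to the symmetric reference-point model
  peq <- c(beta = 0.1, alpha1 = 0.4, alpha_conf = 0.25, alpha_disc = 0.25)
  prp <- c(beta = 0.1, alpha1 = 0.4, alpha2 = 0.25, alpha3 = 0.25)
  st2 <- init_state(); st2$q["A1"] <- 3; st2$q["B"] <- -2; st2$v <- c(1, 0)
  fb <- fb_c("A1", "B", 61, 47)
  expect_equal(relasym_step(st2, fb, peq, "complete")$q,
               rp_step(st2, fb, prp, "complete", "RPA")$q)
})

test_that("opposing learning moves both values with the chosen prediction error", {
  st <- init_state(); st$q["A1"] <- 50; st$q["B"] <- 50
  out <- ol_step(st, fb_p("A1", "B", 64), c(beta = 0.1, alpha1 = 0.2))
  expect_equal(unname(out$q["A1"]), 52.8)
  expect_equal(unname(out$q["B"]), 47.2)
  expect_equal(unname(out$q[c("A2", "C")]), c(0, 0))
  # alpha2 = 0 reduces exactly to simple SQL
  out0 <- ol_step(st, fb_p("A1", "B", 64),
                  c(beta = 0.1, alpha1 = 0.2, alpha2 = 0))
  expect_equal(out0$q, sql_step(st, fb_p("A1", "B", 64),
                                c(beta = 0.1, alpha1 = 0.2))$q)
  # complete feedback: prediction error on the hybrid reward
  outc <- ol_step(init_state(), fb_c("A1", "B", 64, 54),
                  c(beta = 0.1, alpha1 = 0.5, w = 0.5), "complete")
  expect_equal(unname(outc$q["A1"]), 0.5 * 37)
  expect_equal(unname(outc$q["B"]), -0.5 * 37)
})

test_that("equal-rate opposing learning conserves the per-context value sum", {
  cfg <- fig5_config()
  d <- simulate_agent("OL1", c(beta = 0.1, alpha1 = 0.2), cfg, seed = 5)
  tr <- coded_trials(d)
  st <- init_state(0)
  for (i in seq_len(nrow(tr))) {
    fb <- list(chosen = tr$ch[i], unchosen = tr$un[i],
               context = if (tr$ch[i] <= 2) 1L else 2L,
               r_chosen = tr$rch[i], r_unchosen = tr$run[i])
    st <- ol_step(st, fb, c(beta = 0.1, alpha1 = 0.2), "partial")
    expect_equal(unname(st$q["A1"] + st$q["B"]), 0)
    expect_equal(unname(st$q["A2"] + st$q["C"]), 0)
  }
})

test_that("every step rule matches the brute-force oracle on random inputs", {
  set.seed(1234)
  reg <- model_registry()
  for (model in setdiff(names(reg), "SBE")) {
    for (regime in reg[[model]]$regimes) {
      for (rep in 1:60) {
        pa <- random_params(model, regime)
        st <- oracle_init(runif(1, -20, 60))
        st$q <- runif(4, -50, 100); st$v <- runif(2, -50, 100)
        st$n <- runif(4, 0.5, 5)
        tr <- random_trials(1, regime)
        fb_o <- list(ch = tr$ch, un = tr$un, cx = if (tr$ch <= 2) 1 else 2,
                     rch = tr$rch, run = tr$run)
        want <- oracle_step(model, st, fb_o, pa, regime)
        pst <- init_state()
        pst$q[] <- st$q; pst$v <- st$v; pst$n[] <- st$n
        fb <- list(chosen = tr$ch, unchosen = tr$un, r_chosen = tr$rch,
                   r_unchosen = tr$run)
        got <- oppolearn:::.model_step(model, pst, fb, pa, regime)
        expect_equal(unname(got$q), want$q, tolerance = 1e-12)
        expect_equal(unname(got$v), want$v, tolerance = 1e-12)
        expect_equal(unname(got$n), want$n, tolerance = 1e-12)
      }
    }
  }
})
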