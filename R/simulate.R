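#' Simulate one agent playing the three-phase task
#'
#' Plays the learning phase trial by trial (softmax choice, model update,
#' adaptive stopping rule), then the transfer phase with frozen
#' end-of-learning values (choices drawn from softmax, no feedback, no
#' updating), then the estimation phase (frozen values plus response noise,
#' clipped to the 0--100 scale).
#'
#' @param model model key, see [model_registry()].
#' @param params named parameter vector for the model/regime.
#' @param config an [task_config()].
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param subject subject identifier stored in the dataset.
#' @return A behavioral dataset (see [validate_dataset()]) whose `meta`
#'   attribute records the generating model, true parameters, seed, and
#'   whether the run failed the stopping criterion (`excluded`).
#' @examples
#' cfg <- task_config()
#' d <- simulate_agent("OL1", c(beta = 0.05, alpha1 = 0.3), cfg, seed = 42)
#' table(d$phase)
#' @export
simulate_agent <- function(model, params, config, seed,
                           subject = "s1") {
  info <- .model_info(model, config$regime)
  p <- .check_params(params, info)
  set.seed(seed)
  regime <- config$regime
  complete <- regime == "complete"
  state <- init_state(config$q0)
  sched <- build_learning_schedule(config)

  n_max <- config$max_trials
  chosen <- integer(n_max); rch <- numeric(n_max); run_v <- rep(NA_real_, n_max)
  shown_a1 <- numeric(n_max); shown_a2 <- numeric(n_max)
  na1 <- 0L; na2 <- 0L
  u_choice <- runif(n_max)
  excluded <- TRUE
  n_learn <- n_max
  for (t in seq_len(n_max)) {
    lf <- sched$stim_left[t]; rt <- sched$stim_right[t]
    p_lf <- .choice_prob(model, state, lf, rt, p, regime)
    ch <- if (u_choice[t] < p_lf) lf else rt
    un <- if (ch == lf) rt else lf
    r_ch <- draw_reward(ch, config)
    r_un <- if (complete) draw_reward(un, config) else NA_real_
    fb <- list(chosen = ch, unchosen = un, context = sched$context[t],
               r_chosen = r_ch, r_unchosen = r_un)
    state <- .model_step(model, state, fb, p, regime)
    state <- .advance_state(state, fb, regime, t)
    chosen[t] <- ch; rch[t] <- r_ch; run_v[t] <- r_un
    # rewards *shown* for A1/A2 feed the adaptive stopping criterion
    if (ch == 1L) { na1 <- na1 + 1L; shown_a1[na1] <- r_ch }
    if (ch == 3L) { na2 <- na2 + 1L; shown_a2[na2] <- r_ch }
    if (complete) {
      if (un == 1L) { na1 <- na1 + 1L; shown_a1[na1] <- r_un }
      if (un == 3L) { na2 <- na2 + 1L; shown_a2[na2] <- r_un }
    }
    if (na1 > 0L && na2 > 0L && t >= config$min_trials) {
      dec <- stopping_decision(shown_a1[seq_len(na1)], shown_a2[seq_len(na2)],
                               t, config)
      if (dec == "stop") { excluded <- FALSE; n_learn <- t; break }
    }
  }
  li <- seq_len(n_learn)
  learning <- data.frame(
    subject = subject, phase = "learning", trial = li,
    context = c("A1B", "A2C")[sched$context[li]],
    stim_left = .STIM[sched$stim_left[li]],
    stim_right = .STIM[sched$stim_right[li]], choice = .STIM[chosen[li]],
    r_chosen = rch[li], r_unchosen = run_v[li],
    confidence = NA_real_, estimate = NA_real_)

  evals <- build_eval_schedules(config)
  tr <- evals$transfer
  nt <- nrow(tr)
  u_tr <- runif(nt)
  tr_choice <- integer(nt)
  for (i in seq_len(nt)) {
    lf <- tr$stim_left[i]; rt <- tr$stim_right[i]
    p_lf <- .choice_prob(model, state, lf, rt, p, regime)
    tr_choice[i] <- if (u_tr[i] < p_lf) lf else rt
  }
  lo_s <- pmin(tr$stim_left, tr$stim_right)
  hi_s <- pmax(tr$stim_left, tr$stim_right)
  transfer <- data.frame(
    subject = subject, phase = "transfer", trial = seq_len(nt),
    context = paste0(.STIM[lo_s], .STIM[hi_s]),
    stim_left = .STIM[tr$stim_left], stim_right = .STIM[tr$stim_right],
    choice = .STIM[tr_choice], r_chosen = NA_real_, r_unchosen = NA_real_,
    confidence = NA_real_, estimate = NA_real_)

  vals <- .state_values(model, state, p)
  es <- evals$estimation
  resp <- vals[es$stim] + rnorm(nrow(es), 0, config$estimate_noise_sd)
  estimation <- data.frame(
    subject = subject, phase = "estimation", trial = seq_len(nrow(es)),
    context = .STIM[es$stim], stim_left = .STIM[es$stim],
    stim_right = NA_character_, choice = NA_character_,
    r_chosen = NA_real_, r_unchosen = NA_real_, confidence = NA_real_,
    estimate = pmin(100, pmax(0, resp)))

  out <- rbind(learning, transfer, estimation)
  rownames(out) <- NULL
  attr(out, "regime") <- regime
  meta <- list(list(model = model, params = as.list(p), seed = seed,
                    excluded = excluded, n_learning = n_learn))
  names(meta) <- subject
  attr(out, "meta") <- meta
  out
}

# latent per-stimulus values used for transfer/estimation responses
.state_values <- function(model, state, params) {
  if (model != "SBE") return(state$q)
  vapply(1:4, function(s) {
    r <- state$hist_r[[s]]; ti <- state$hist_t[[s]]
    if (!length(r)) return(state$q0)
    w <- params[["alpha1"]] * (1 - params[["alpha1"]])^(state$t + 1L - ti)
    sum(r * w / sum(w))
  }, numeric(1))
}

#' Beta-distribution parameter samplers for synthetic cohorts
#'
#' `beta_from_moments()` converts a (mean, SD) pair on \[0, 1\] to Beta shape
#' parameters by moment matching, erroring when the SD is infeasible for the
#' mean.  `param_sampler()` builds a sampling function for a whole parameter
#' vector from either explicit shapes or a moments table.
#'
#' @param mean,sd moments of one parameter on \[0, 1\].
#' @return `beta_from_moments()`: named numeric `c(shape1, shape2)`.
#' @examples
#' beta_from_moments(0.26, 0.2)
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("infeasible moments: sd ", sd, " too large for mean ", mean,
         " on [0, 1]", call. = FALSE)
  common <- mean * (1 - mean) / v - 1
  c(shape1 = mean * common, shape2 = (1 - mean) * common)
}

#' @rdname beta_from_moments
#' @param moments data.frame with columns `param`, `mean`, `sd` (one row per
#'   model parameter), or a named list of `c(shape1, shape2)` vectors.
#' @param model model key; when given, OL2's `alpha2 <= alpha1` constraint is
#'   enforced by resampling.
#' @return `param_sampler()`: a `function(n)` returning an `n`-row data.frame
#'   of in-bounds parameter draws.
#' @export
param_sampler <- function(moments, model = NULL) {
  shapes <- if (is.data.frame(moments)) {
    stopifnot(all(c("param", "mean", "sd") %in% names(moments)))
    sh <- lapply(seq_len(nrow(moments)), function(i)
      tryCatch(beta_from_moments(moments$mean[i], moments$sd[i]),
               error = function(e) stop("parameter ", moments$param[i], ": ",
                                        conditionMessage(e), call. = FALSE)))
    names(sh) <- moments$param
    sh
  } else moments
  function(n) {
    draw <- function() {
      out <- lapply(shapes, function(s) rbeta(n, s[["shape1"]], s[["shape2"]]))
      as.data.frame(out)
    }
    d <- draw()
    if (!is.null(model) && model == "OL2") {
      for (i in 1:100) {
        bad <- d$alpha2 > d$alpha1
        if (!any(bad)) break
        repl <- draw()
        d[bad, ] <- repl[bad, ]
      }
      bad <- d$alpha2 > d$alpha1
      # last resort keeps the draw in-bounds without biasing alpha1
      d$alpha2[bad] <- d$alpha1[bad] * runif(sum(bad))
    }
    d
  }
}

#' Default generating-parameter moments per model and regime
#'
#' Mean and SD of each free parameter used when sampling synthetic cohorts.
#' For the main model space (SQL, RPA, Dif, Hyb, OL1, OL2) these are the
#' cohort-level estimates obtained on the original behavioral data; for the
#' remaining families, which have no published cohort estimates for this
#' task, they are fixed field-typical values (see the methods vignette).
#'
#' @param model model key.
#' @param regime `"partial"` or `"complete"`.
#' @return data.frame with columns `param`, `mean`, `sd`.
#' @export
default_param_moments <- function(model, regime = c("partial", "complete")) {
  regime <- match.arg(regime)
  info <- .model_info(model, regime)
  tab <- list(
    partial = list(
      SQL = c(beta = 0.07, alpha1 = 0.25, beta_sd = 0.03, alpha1_sd = 0.26),
      RPA = c(beta = 0.12, alpha1 = 0.26, alpha2 = 0.34,
              beta_sd = 0.08, alpha1_sd = 0.27, alpha2_sd = 0.30),
      Hyb = c(beta = 0.06, alpha1 = 0.37, w = 0.55,
              beta_sd = 0.04, alpha1_sd = 0.29, w_sd = 0.37),
      OL1 = c(beta = 0.02, alpha1 = 0.26, beta_sd = 0.02, alpha1_sd = 0.20),
      OL2 = c(beta = 0.03, alpha1 = 0.32, alpha2 = 0.21,
              beta_sd = 0.02, alpha1_sd = 0.23, alpha2_sd = 0.18)),
    complete = list(
      SQL = c(beta = 0.12, alpha1 = 0.14, beta_sd = 0.09, alpha1_sd = 0.16),
      RPA = c(beta = 0.37, alpha1 = 0.10, alpha2 = 0.11, alpha3 = 0.35,
              beta_sd = 0.24, alpha1_sd = 0.12, alpha2_sd = 0.13,
              alpha3_sd = 0.30),
      Dif = c(beta = 0.37, alpha1 = 0.09, beta_sd = 0.23, alpha1_sd = 0.08),
      Hyb = c(beta = 0.20, alpha1 = 0.21, w = 0.28,
              beta_sd = 0.15, alpha1_sd = 0.15, w_sd = 0.23),
      OL1 = c(beta = 0.11, alpha1 = 0.22, w = 0.28,
              beta_sd = 0.12, alpha1_sd = 0.15, w_sd = 0.17),
      OL2 = c(beta = 0.10, alpha1 = 0.26, alpha2 = 0.19, w = 0.32,
              beta_sd = 0.10, alpha1_sd = 0.14, alpha2_sd = 0.16,
              w_sd = 0.19))
  )
  # field-typical moments for families without published cohort estimates;
  # note FQL's alpha2 is a *retention* factor (unchosen value keeps
  # alpha2 * Q_un per trial): fitted retention in the forgetting-Q-learning
  # literature is high, so its generator is centred near 0.9, unlike the
  # learning-rate alpha2 of the reference-point models
  filler <- list(
    beta = c(if (regime == "partial") 0.07 else 0.12,
             if (regime == "partial") 0.04 else 0.09),
    alpha1 = c(0.25, 0.20), alpha2 = c(0.30, 0.20), alpha3 = c(0.25, 0.20),
    w = c(0.40, 0.25), phi = c(0.60, 0.20), rho = c(0.60, 0.20),
    delta_imit = c(0.50, 0.25), alpha_conf = c(0.35, 0.20),
    alpha_disc = c(0.20, 0.15))
  special <- list(FQL = list(alpha2 = c(0.90, 0.08)),
                  SBE = list(alpha1 = c(0.30, 0.20)))
  ent <- tab[[regime]][[model]]
  out <- data.frame(param = info$par_names, mean = NA_real_, sd = NA_real_)
  for (i in seq_len(nrow(out))) {
    pn <- out$param[i]
    if (!is.null(ent) && pn %in% names(ent)) {
      out$mean[i] <- ent[[pn]]; out$sd[i] <- ent[[paste0(pn, "_sd")]]
    } else if (!is.null(special[[model]]) && pn %in% names(special[[model]])) {
      out$mean[i] <- special[[model]][[pn]][1]
      out$sd[i] <- special[[model]][[pn]][2]
    } else {
      out$mean[i] <- filler[[pn]][1]; out$sd[i] <- filler[[pn]][2]
    }
  }
  # clip SDs that are infeasible for a [0,1]-supported Beta with this mean
  cap <- sqrt(out$mean * (1 - out$mean)) * 0.95
  out$sd <- pmin(out$sd, cap)
  out
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject parameters from `sampler` (or from the model's
#' [default_param_moments()]) and simulates each subject independently with
#' a child seed derived from `seed`.
#'
#' @inheritParams simulate_agent
#' @param n_subjects cohort size; 0 gives an empty cohort.
#' @param sampler a `function(n)` returning an `n`-row parameter data.frame
#'   (see [param_sampler()]), a moments data.frame, or `NULL` for the
#'   model's defaults.
#' @param id_prefix prefix of generated subject identifiers.
#' @return one behavioral data.frame containing all subjects, with
#'   per-subject `meta` entries.
#' @export
simulate_cohort <- function(model, n_subjects, config, seed,
                            sampler = NULL, id_prefix = "s") {
  if (is.null(sampler))
    sampler <- param_sampler(default_param_moments(model, config$regime),
                             model = model)
  if (is.data.frame(sampler))
    sampler <- param_sampler(sampler, model = model)
  set.seed(seed)
  if (n_subjects == 0L) {
    out <- data.frame(subject = character(0), phase = character(0),
                      trial = integer(0), context = character(0),
                      stim_left = character(0), stim_right = character(0),
                      choice = character(0), r_chosen = numeric(0),
                      r_unchosen = numeric(0), confidence = numeric(0),
                      estimate = numeric(0))
    attr(out, "regime") <- config$regime
    attr(out, "meta") <- list()
    return(out)
  }
  pars <- sampler(n_subjects)
  info <- .model_info(model, config$regime)
  miss <- setdiff(info$par_names, names(pars))
  if (length(miss))
    stop("sampler does not provide parameter(s): ",
         paste(miss, collapse = ", "))
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_subjects))
  sets <- lapply(seq_len(n_subjects), function(i) {
    pv <- unlist(pars[i, info$par_names, drop = FALSE])
    simulate_agent(model, pv, config, seed = seeds[i], subject = ids[i])
  })
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  attr(out, "regime") <- config$regime
  attr(out, "meta") <- do.call(c, lapply(sets, attr, "meta"))
  out
}

# fast two-option opposing-learning simulator on a single context;
# rewards are pre-generated truncated-normal draws for both options
.sim_pair_ol <- function(alpha1, alpha2, beta, mu, sigma, n_trials, q0 = 0) {
  lo <- pmax(0, mu - 3 * sigma); hi <- pmin(100, mu + 3 * sigma)
  r1 <- .draw_trunc(n_trials, mu[1], sigma[1], lo[1], hi[1])
  r2 <- .draw_trunc(n_trials, mu[2], sigma[2], lo[2], hi[2])
  u <- runif(n_trials)
  q1 <- q2 <- numeric(n_trials)
  ch <- integer(n_trials)
  a <- q0; b <- q0
  for (t in seq_len(n_trials)) {
    x <- beta * (a - b)
    p1 <- if (x >= 0) 1 / (1 + exp(-x)) else { e <- exp(x); e / (1 + e) }
    if (u[t] < p1) {
      d <- r1[t] - a; a <- a + alpha1 * d; b <- b - alpha2 * d; ch[t] <- 1L
    } else {
      d <- r2[t] - b; b <- b + alpha1 * d; a <- a - alpha2 * d; ch[t] <- 2L
    }
    q1[t] <- a; q2[t] <- b
  }
  list(q1 = q1, q2 = q2, choice = ch)
}

#' Correlation between paired option values under opposing learning
#'
#' Simulates the opposing-learning model on one two-option context and
#' measures the Pearson correlation between the two learned value series.
#' Opposing learning couples the values through the shared prediction error,
#' and the stationary correlation follows `-alpha2 / alpha1` (0 for
#' one-sided updating, exactly -1 at equal rates, where the values are
#' antisymmetric by construction).
#'
#' With `estimator = "within"` the correlation is computed per run over the
#' trial series after `burn_in` trials and averaged across runs.  Note that
#' this estimator approaches the stationary law only when the series is much
#' longer than the mixing time of the slowly decaying sum mode (rate
#' `(alpha1 - alpha2) / 2` per trial), so intermediate rate ratios need long
#' runs; the endpoints 0 and `alpha1` are unbiased already at 1,000 trials.
#' `estimator = "ensemble"` instead correlates the two values across runs at
#' the final trial.
#'
#' @param alpha1,alpha2 chosen/unchosen learning rates (`alpha2 <= alpha1`).
#' @param beta softmax inverse temperature.
#' @param mu,sigma means and common SD of the two reward distributions.
#' @param n_trials trials per run; @param n_runs independent runs (>= 2 for
#'   a standard error).
#' @param burn_in leading trials discarded before correlating.
#' @param estimator `"within"` (default) or `"ensemble"`, see Details.
#' @param seed integer seed.
#' @param q0 initial value.
#' @return list with `mean`, `se`, `per_run` (within-run estimates; `NA` for
#'   the ensemble estimator), `estimator`, and the predicted stationary
#'   correlation `law = -alpha2/alpha1`.
#' @examples
#' \donttest{
#' qvalue_correlation_experiment(0.2, 0.2, 0.1, seed = 1)$mean  # ~ -1
#' }
#' @export
qvalue_correlation_experiment <- function(alpha1, alpha2, beta,
                                          mu = c(7, 5), sigma = 1,
                                          n_trials = 1000L, n_runs = 20L,
                                          burn_in = 50L,
                                          estimator = c("within", "ensemble"),
                                          seed = NULL, q0 = 0) {
  estimator <- match.arg(estimator)
  stopifnot(alpha1 > 0, alpha2 >= 0, alpha2 <= alpha1,
            n_trials - burn_in >= 200L)
  if (!is.null(seed)) set.seed(seed)
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  runs <- lapply(seq_len(n_runs), function(.)
    .sim_pair_ol(alpha1, alpha2, beta, mu, sigma, n_trials, q0))
  keep <- (burn_in + 1L):n_trials
  if (estimator == "within") {
    per_run <- vapply(runs, function(r) cor(r$q1[keep], r$q2[keep]),
                      numeric(1))
    m <- mean(per_run)
    se <- if (n_runs >= 2L) sd(per_run) / sqrt(n_runs) else NA_real_
  } else {
    fin1 <- vapply(runs, function(r) r$q1[n_trials], numeric(1))
    fin2 <- vapply(runs, function(r) r$q2[n_trials], numeric(1))
    per_run <- rep(NA_real_, n_runs)
    m <- cor(fin1, fin2)
    se <- NA_real_
  }
  if (is.na(se) && n_runs < 2L)
    warning("n_runs < 2: no Monte-Carlo standard error")
  list(mean = m, se = se, per_run = per_run, estimator = estimator,
       law = -alpha2 / alpha1)
}

#' Learning performance across a grid of opposing-learning settings
#'
#' For every combination of option pair, inverse temperature, chosen
#' learning rate, and rate ratio `alpha2/alpha1`, simulates two-option
#' opposing-learning runs and tabulates the fraction of trials on which the
#' higher-mean option was chosen.  Increasing the ratio from 0 (standard
#' Q-learning) to 1 sharpens the contrast between the two learned values and
#' raises performance at moderate `beta`.
#'
#' @param pairs list of length-2 mean vectors (higher mean first).
#' @param sigma common reward SD.
#' @param betas,alpha1s,ratios parameter grids (ratios in \[0, 1\]).
#' @param n_trials trials per run; @param n_reps repetitions per cell.
#' @param seed integer seed.
#' @param q0 initial value.
#' @return data.frame with one row per cell: grid coordinates, `mean`, `sd`,
#'   and Monte-Carlo `se` of performance across repetitions.
#' @examples
#' \donttest{
#' run_performance_grid(ratios = c(0, 1), n_reps = 20, seed = 1)
#' }
#' @export
run_performance_grid <- function(pairs = list(c(10, 7)), sigma = 1,
                                 betas = 0.1, alpha1s = 0.2,
                                 ratios = c(0, 0.5, 1),
                                 n_trials = 200L, n_reps = 200L,
                                 seed = NULL, q0 = 0) {
  stopifnot(length(pairs) >= 1, length(betas) >= 1, length(alpha1s) >= 1,
            length(ratios) >= 1, all(ratios >= 0 & ratios <= 1))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(pair = seq_along(pairs), beta = betas,
                      alpha1 = alpha1s, ratio = ratios,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mu <- pairs[[grid$pair[i]]]
    adv <- which.max(mu)
    perf <- vapply(seq_len(n_reps), function(.) {
      r <- .sim_pair_ol(grid$alpha1[i], grid$ratio[i] * grid$alpha1[i],
                        grid$beta[i], mu, rep(sigma, 2), n_trials, q0)
      mean(r$choice == adv)
    }, numeric(1))
    data.frame(mu1 = mu[1], mu2 = mu[2], beta = grid$beta[i],
               alpha1 = grid$alpha1[i], ratio = grid$ratio[i],
               mean = mean(perf), sd = sd(perf),
               se = sd(perf) / sqrt(n_reps))
  })
  do.call(rbind, res)
}
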