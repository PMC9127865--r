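#' Learning-phase negative log-likelihood
#'
#' Replays one subject's answered learning trials under a model, updating
#' the agent state trial by trial and scoring each observed choice with the
#' softmax probability implied by the pre-update values (the sample-based
#' episodic model scores choices with its recency-weighted sampling mixture
#' instead).  Missed trials carry no outcome in this task, so they
#' contribute neither a likelihood term nor a state update.
#'
#' @param model model key, see [model_registry()].
#' @param params named parameter vector.
#' @param data behavioral dataset.
#' @param subject subject id; may be omitted for single-subject data.
#' @param regime feedback regime; defaults to the dataset attribute.
#' @param q0 initial option value.
#' @param engine `"cpp"` (compiled replay, default) or `"r"` (reference R
#'   step functions); both produce identical values.
#' @return negative log-likelihood in nats (>= 0).
#' @export
learning_nll <- function(model, params, data, subject = NULL,
                         regime = attr(data, "regime"), q0 = 0,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  info <- .model_info(model, regime)
  p <- .check_params(params, info)
  subject <- .one_subject(data, subject)
  coded <- .coded_learning(data, subject)
  if (is.null(coded)) stop("no answered learning trials for subject ", subject)
  if (regime == "complete" && anyNA(coded$r_un))
    stop("complete feedback requires r_unchosen on every answered trial")
  if (engine == "cpp") {
    .ol_replay_cpp(info$id, as.numeric(p), coded$chosen, coded$unchosen,
                   coded$context, coded$tidx, coded$r_ch,
                   ifelse(is.na(coded$r_un), 0, coded$r_un),
                   regime == "complete", q0, TRUE, FALSE)$nll
  } else {
    .replay_r(model, p, coded, regime, q0)$nll
  }
}

.one_subject <- function(data, subject) {
  subs <- unique(data$subject)
  if (is.null(subject)) {
    if (length(subs) != 1L)
      stop("data contains ", length(subs),
           " subjects; specify `subject`")
    return(subs)
  }
  if (!subject %in% subs) stop("subject ", subject, " not in data")
  subject
}

# pure-R replay: reference implementation of the likelihood
.replay_r <- function(model, params, coded, regime, q0) {
  state <- init_state(q0)
  nll <- 0
  trial_p <- numeric(coded$n)
  for (i in seq_len(coded$n)) {
    ch <- coded$chosen[i]; un <- coded$unchosen[i]
    if (model == "SBE") {
      pr <- sbe_trial_likelihood(state$hist_r[[ch]], state$hist_t[[ch]],
                                 state$hist_r[[un]], state$hist_t[[un]],
                                 coded$tidx[i], params[["alpha1"]],
                                 params[["beta"]], q0 = q0)
      nll <- nll - log(pr)
    } else {
      nll <- nll - .log_softmax_prob(state$q[ch], state$q[un],
                                     params[["beta"]])
      pr <- softmax_choice_prob(state$q[ch], state$q[un], params[["beta"]])
    }
    trial_p[i] <- pr
    fb <- list(chosen = ch, unchosen = un, context = coded$context[i],
               r_chosen = coded$r_ch[i], r_unchosen = coded$r_un[i])
    state <- .model_step(model, state, fb, params, regime)
    state <- .advance_state(state, fb, regime, coded$tidx[i])
  }
  list(nll = unname(nll), state = state, trial_p = unname(trial_p))
}

#' Information criteria on the nats scale
#'
#' `bic = 2 * nll + k * log(n)` and `aic = 2 * nll + 2 * k`.  BIC is the
#' quantity handed to the random-effects model comparison because the
#' adaptive stopping rule gives every subject a different trial count.
#'
#' @param nll negative log-likelihood (nats).
#' @param k number of free parameters.
#' @param n number of trials entering the likelihood.
#' @return named numeric `c(bic, aic)`.
#' @examples
#' information_criteria(100 * log(2), k = 2, n = 100)
#' @export
information_criteria <- function(nll, k, n) {
  stopifnot(n >= 1, k >= 0)
  c(bic = 2 * nll + k * log(n), aic = 2 * nll + 2 * k)
}

#' Maximum a posteriori fit of one subject
#'
#' Minimizes the learning-phase negative log-likelihood plus the negative
#' log of a weakly informative Beta(1.2, 1.2) prior on every parameter, over
#' the unit box, restarting from `n_restarts` prior-sampled initial points
#' and keeping the best optimum.  The inverse temperature is fitted on
#' \[0, 1\] (option values span 0--100 points, so plausible `beta` values are
#' far below 1).  For OL2 the constraint `alpha2 <= alpha1` is enforced by
#' optimizing the ratio `alpha2 / alpha1` on \[0, 1\].
#'
#' @inheritParams learning_nll
#' @param n_restarts number of optimizer restarts (>= 1).
#' @param seed integer seed for the restart draws.
#' @param prior_shape `c(shape1, shape2)` of the Beta prior.
#' @param control passed to [stats::optim()] (L-BFGS-B).
#' @return list with elements `params` (MAP estimates on the model scale),
#'   `objective` (penalized NLL at the optimum), `nll` (unpenalized),
#'   `bic`, `aic`, `n`, `k`, `n_restarts`, `best_restart`, `convergence`.
#' @export
map_fit <- function(model, data, subject = NULL,
                    regime = attr(data, "regime"), n_restarts = 10L,
                    seed = 1L, q0 = 0, prior_shape = c(1.2, 1.2),
                    control = list(factr = 1e7, maxit = 200L)) {
  stopifnot(n_restarts >= 1L)
  info <- .model_info(model, regime)
  subject <- .one_subject(data, subject)
  coded <- .coded_learning(data, subject)
  if (is.null(coded)) stop("no answered learning trials for subject ", subject)
  complete <- regime == "complete"
  r_un <- ifelse(is.na(coded$r_un), 0, coded$r_un)
  if (complete && anyNA(coded$r_un))
    stop("complete feedback requires r_unchosen on every answered trial")

  # OL2: optimize (beta, alpha1, kappa [, w]) with alpha2 = kappa * alpha1
  is_ol2 <- model == "OL2"
  fit_names <- if (is_ol2) sub("^alpha2$", "kappa", info$par_names) else info$par_names
  to_model <- function(theta) {
    names(theta) <- fit_names
    if (is_ol2) {
      out <- theta
      names(out) <- info$par_names
      out[["alpha2"]] <- theta[["kappa"]] * theta[["alpha1"]]
      out
    } else theta
  }
  npar <- length(fit_names)
  objective <- function(theta) {
    pm <- to_model(theta)
    nll <- .ol_replay_cpp(info$id, as.numeric(pm), coded$chosen,
                          coded$unchosen, coded$context, coded$tidx,
                          coded$r_ch, r_un, complete, q0, TRUE, FALSE)$nll
    nll - sum(dbeta(theta, prior_shape[1], prior_shape[2], log = TRUE))
  }

  set.seed(seed)
  starts <- matrix(rbeta(n_restarts * npar, prior_shape[1], prior_shape[2]),
                   nrow = n_restarts)
  eps <- 1e-8
  starts <- pmin(pmax(starts, eps), 1 - eps)
  best <- NULL; best_i <- NA_integer_; fails <- character(0)
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = rep(eps, npar), upper = rep(1 - eps, npar),
            control = control),
      error = function(e) e)
    if (inherits(res, "error")) { fails <- c(fails, conditionMessage(res)); next }
    if (is.null(best) || res$value < best$value) { best <- res; best_i <- i }
  }
  if (is.null(best))
    stop("all ", n_restarts, " restarts failed for subject ", subject,
         " / model ", model, ": ", paste(unique(fails), collapse = "; "))
  pm <- to_model(best$par)
  nll <- .ol_replay_cpp(info$id, as.numeric(pm), coded$chosen, coded$unchosen,
                        coded$context, coded$tidx, coded$r_ch, r_un,
                        complete, q0, TRUE, FALSE)$nll
  ic <- information_criteria(nll, info$k, coded$n)
  list(subject = subject, model = model, params = pm,
       objective = best$value, nll = nll, bic = ic[["bic"]],
       aic = ic[["aic"]], n = coded$n, k = info$k,
       n_restarts = n_restarts, best_restart = best_i,
       convergence = best$convergence)
}

#' Transfer-phase predictive negative log-likelihood
#'
#' Replays the learning phase at the given (typically MAP) parameters to
#' obtain end-of-learning values, then scores every answered transfer choice
#' with those frozen values and the same inverse temperature.  Returns both
#' the sum over all transfer pairs and the sum over the (A1, A2) pair alone,
#' the pair that isolates the context-induced transfer bias.
#'
#' @inheritParams learning_nll
#' @return named numeric `c(total, a1a2)` in nats.
#' @export
transfer_nll <- function(model, params, data, subject = NULL,
                         regime = attr(data, "regime"), q0 = 0) {
  info <- .model_info(model, regime)
  p <- .check_params(params, info)
  subject <- .one_subject(data, subject)
  coded <- .coded_learning(data, subject)
  if (is.null(coded)) stop("no answered learning trials for subject ", subject)
  tcoded <- .coded_transfer(data, subject)
  if (is.null(tcoded)) stop("no transfer phase for subject ", subject)
  rep_out <- .replay_r(model, p, coded, regime, q0)
  state <- rep_out$state
  lp <- vapply(seq_len(tcoded$n), function(i) {
    ch <- tcoded$chosen[i]; un <- tcoded$unchosen[i]
    if (model == "SBE")
      log(sbe_trial_likelihood(state$hist_r[[ch]], state$hist_t[[ch]],
                               state$hist_r[[un]], state$hist_t[[un]],
                               state$t + 1L, p[["alpha1"]], p[["beta"]],
                               q0 = q0))
    else .log_softmax_prob(state$q[ch], state$q[un], p[["beta"]])
  }, numeric(1))
  a1a2 <- (tcoded$chosen == 1L & tcoded$unchosen == 3L) |
    (tcoded$chosen == 3L & tcoded$unchosen == 1L)
  c(total = -sum(lp), a1a2 = -sum(lp[a1a2]))
}

#' Fit a learning model to a behavioral cohort
#'
#' The central fitting function: every subject in `data` is fitted
#' independently by maximum a posteriori ([map_fit()]), and each fit is
#' scored in-sample (learning NLL, BIC, AIC) and out-of-sample on the
#' transfer phase ([transfer_nll()]).
#'
#' @inheritParams map_fit
#' @param data behavioral dataset with one or more subjects.
#' @return An object of class `"rl_fit"`: a list with `fits` (one row per
#'   subject: MAP parameters, `learning_nll`, `map_objective`, `bic`, `aic`,
#'   `n_trials`, `transfer_nll`, `transfer_nll_a1a2`, `best_restart`,
#'   `convergence`), `model`, `regime`, `par_names`, and the data used.
#'   Supported methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `simulate`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' cfg <- task_config()
#' d <- simulate_cohort("OL1", 3, cfg, seed = 7)
#' f <- rl_fit(d, "OL1", n_restarts = 3, seed = 1)
#' summary(f)
#' }
#' @export
rl_fit <- function(data, model, regime = attr(data, "regime"),
                   n_restarts = 10L, seed = 1L, q0 = 0,
                   prior_shape = c(1.2, 1.2),
                   control = list(factr = 1e7, maxit = 200L)) {
  info <- .model_info(model, regime)
  subs <- unique(data$subject)
  if (!length(subs)) stop("no subjects in data")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(subs))
  rows <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    fit <- map_fit(model, data, subs[i], regime, n_restarts,
                   seed = sub_seeds[i], q0 = q0, prior_shape = prior_shape,
                   control = control)
    tn <- tryCatch(transfer_nll(model, fit$params, data, subs[i], regime, q0),
                   error = function(e) c(total = NA_real_, a1a2 = NA_real_))
    rows[[i]] <- data.frame(subject = subs[i],
                            as.list(fit$params),
                            learning_nll = fit$nll,
                            map_objective = fit$objective,
                            bic = fit$bic, aic = fit$aic,
                            n_trials = fit$n,
                            transfer_nll = tn[["total"]],
                            transfer_nll_a1a2 = tn[["a1a2"]],
                            best_restart = fit$best_restart,
                            convergence = fit$convergence)
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  structure(list(fits = fits, model = model, regime = regime,
                 par_names = info$par_names, k = info$k, q0 = q0,
                 n_restarts = n_restarts, data = data,
                 call = match.call()),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("Model fit:", x$model, "(", x$regime, "feedback ),",
      nrow(x$fits), "subject(s)\n")
  cat(sprintf("  mean learning NLL %.2f | mean BIC %.2f | mean AIC %.2f\n",
              mean(x$fits$learning_nll), mean(x$fits$bic),
              mean(x$fits$aic)))
  if (!all(is.na(x$fits$transfer_nll)))
    cat(sprintf("  transfer NLL (all pairs) %.2f | (A1,A2) %.2f\n",
                mean(x$fits$transfer_nll, na.rm = TRUE),
                mean(x$fits$transfer_nll_a1a2, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.rl_fit <- function(object, ...) {
  cf <- coef(object)
  par_tab <- data.frame(param = colnames(cf),
                        mean = colMeans(cf),
                        sd = apply(cf, 2, sd), row.names = NULL)
  out <- list(model = object$model, regime = object$regime,
              n_subjects = nrow(object$fits), params = par_tab,
              mean_nll = mean(object$fits$learning_nll),
              mean_bic = mean(object$fits$bic),
              mean_aic = mean(object$fits$aic),
              mean_transfer = mean(object$fits$transfer_nll, na.rm = TRUE),
              mean_transfer_a1a2 = mean(object$fits$transfer_nll_a1a2,
                                        na.rm = TRUE))
  class(out) <- "summary.rl_fit"
  out
}

#' @export
print.summary.rl_fit <- function(x, ...) {
  cat("Model:", x$model, "| regime:", x$regime,
      "| subjects:", x$n_subjects, "\n\nParameters (cohort mean +/- SD):\n")
  for (i in seq_len(nrow(x$params)))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", x$params$param[i],
                x$params$mean[i], x$params$sd[i]))
  cat(sprintf("\nMean learning NLL %.2f | BIC %.2f | AIC %.2f\n",
              x$mean_nll, x$mean_bic, x$mean_aic))
  if (!is.nan(x$mean_transfer))
    cat(sprintf("Mean transfer NLL: all pairs %.2f, (A1,A2) pair %.2f\n",
                x$mean_transfer, x$mean_transfer_a1a2))
  invisible(x)
}

#' @export
coef.rl_fit <- function(object, ...) {
  m <- as.matrix(object$fits[, object$par_names, drop = FALSE])
  rownames(m) <- object$fits$subject
  m
}

#' @export
logLik.rl_fit <- function(object, ...) {
  structure(-sum(object$fits$learning_nll),
            df = object$k * nrow(object$fits),
            nobs = sum(object$fits$n_trials), class = "logLik")
}

#' @export
predict.rl_fit <- function(object, newdata = NULL,
                           phase = c("transfer", "learning"),
                           type = c("prob", "nll"), ...) {
  phase <- match.arg(phase); type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  subs <- intersect(unique(data$subject), object$fits$subject)
  if (!length(subs)) stop("no fitted subjects found in data")
  rows <- lapply(subs, function(sj) {
    p <- unlist(object$fits[object$fits$subject == sj, object$par_names])
    coded <- .coded_learning(data, sj)
    rep_out <- .replay_r(object$model, p, coded, object$regime, object$q0)
    if (phase == "learning") {
      data.frame(subject = sj, trial = coded$tidx,
                 chosen = .STIM[coded$chosen],
                 unchosen = .STIM[coded$unchosen], p_choice = rep_out$trial_p)
    } else {
      tc <- .coded_transfer(data, sj)
      st <- rep_out$state
      pr <- vapply(seq_len(tc$n), function(i) {
        if (object$model == "SBE")
          sbe_trial_likelihood(st$hist_r[[tc$chosen[i]]],
                               st$hist_t[[tc$chosen[i]]],
                               st$hist_r[[tc$unchosen[i]]],
                               st$hist_t[[tc$unchosen[i]]],
                               st$t + 1L, p[["alpha1"]], p[["beta"]],
                               q0 = object$q0)
        else softmax_choice_prob(st$q[tc$chosen[i]], st$q[tc$unchosen[i]],
                                 p[["beta"]])
      }, numeric(1))
      data.frame(subject = sj, trial = seq_len(tc$n),
                 chosen = .STIM[tc$chosen], unchosen = .STIM[tc$unchosen],
                 p_choice = pr)
    }
  })
  out <- do.call(rbind, rows)
  if (type == "nll") {
    agg <- tapply(-log(out$p_choice), out$subject, sum)
    return(data.frame(subject = names(agg), nll = as.numeric(agg),
                      row.names = NULL))
  }
  out
}

#' @export
residuals.rl_fit <- function(object, ...) {
  pr <- predict(object, phase = "learning", type = "prob")
  d <- object$data
  lrn <- d[d$phase == "learning" & !is.na(d$choice), ]
  lrn <- lrn[order(match(lrn$subject, unique(pr$subject))), ]
  chose_left <- lrn$choice == lrn$stim_left
  p_left <- ifelse(chose_left, pr$p_choice, 1 - pr$p_choice)
  data.frame(subject = pr$subject, trial = pr$trial,
             residual = as.numeric(chose_left) - p_left)
}

#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- task_config(regime = object$regime, q0 = object$q0)
  seeds <- matrix(sample.int(.Machine$integer.max, nsim * nrow(object$fits)),
                  nrow = nsim)
  out <- lapply(seq_len(nsim), function(s) {
    sets <- lapply(seq_len(nrow(object$fits)), function(i) {
      p <- unlist(object$fits[i, object$par_names])
      simulate_agent(object$model, p, cfg, seed = seeds[s, i],
                     subject = object$fits$subject[i])
    })
    d <- do.call(rbind, sets)
    attr(d, "regime") <- object$regime
    attr(d, "meta") <- do.call(c, lapply(sets, attr, "meta"))
    d
  })
  if (nsim == 1L) out[[1]] else out
}

#' @export
plot.rl_fit <- function(x, bin = 10L, seed = 1L, ...) {
  obs <- .binned_curves(x$data, bin)
  sim <- .binned_curves(simulate(x, seed = seed), bin)
  ylim <- c(0, 1)
  matplot(obs$bin, cbind(obs$A1B, obs$A2C), type = "l", lty = 1,
          col = c("forestgreen", "sienna"), ylim = ylim,
          xlab = paste0("trial bin (", bin, " trials)"),
          ylab = "P(advantageous choice)",
          main = paste("Learning curves:", x$model), ...)
  matplot(sim$bin, cbind(sim$A1B, sim$A2C), type = "l", lty = 2,
          col = c("forestgreen", "sienna"), add = TRUE)
  abline(h = 0.5, col = "grey70")
  legend("bottomright", bty = "n", lty = c(1, 1, 2),
         col = c("forestgreen", "sienna", "grey30"),
         legend = c("A1 vs B (data)", "A2 vs C (data)", "model"))
  invisible(x)
}

# cohort-average binned learning curves per context
.binned_curves <- function(data, bin = 10L) {
  lrn <- data[data$phase == "learning" & !is.na(data$choice), ]
  adv <- ifelse(lrn$context == "A1B", "A1", "A2")
  correct <- as.numeric(lrn$choice == adv)
  # per-subject within-context trial rank, then bin
  key <- paste(lrn$subject, lrn$context)
  rank_in <- ave(seq_len(nrow(lrn)), key, FUN = seq_along)
  b <- ceiling(rank_in / bin)
  agg <- tapply(correct, list(b, lrn$context), mean)
  out <- data.frame(bin = as.integer(rownames(agg)))
  out$A1B <- if ("A1B" %in% colnames(agg)) agg[, "A1B"] else NA_real_
  out$A2C <- if ("A2C" %in% colnames(agg)) agg[, "A2C"] else NA_real_
  out
}
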