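#' Task configuration for the three-phase instrumental learning task
#'
#' Defines the two learning contexts (stimulus pairs (A1, B) and (A2, C)),
#' their reward distributions, the adaptive learning-phase length, and the
#' transfer/estimation schedules.  Rewards are truncated normal draws on the
#' displayed 0--100 point scale: each option's bounds are
#' `[max(0, mu - 3*sigma), min(100, mu + 3*sigma)]`.
#'
#' The learning phase runs for at least `min_trials` trials and then stops as
#' soon as the experienced mean rewards of A1 and A2 differ by less than
#' `stop_tolerance`; a run that has not met the criterion by `max_trials` is
#' flagged excluded (mirroring the exclusion rule applied to human subjects).
#'
#' @param mu named numeric(4), mean reward (points) of A1, B, A2, C.
#' @param sigma numeric(4) (or scalar), reward standard deviations.
#' @param min_trials,max_trials bounds on the learning-phase length.
#' @param stop_tolerance stopping threshold (points) on |mean(A1) - mean(A2)|.
#' @param transfer_repeats repetitions of each of the 6 unordered pairs.
#' @param estimation_repeats repetitions of each stimulus in the estimation
#'   phase.
#' @param regime `"partial"` (only the chosen outcome shown) or `"complete"`
#'   (both outcomes shown).
#' @param q0 initial option/context value (points).  0 by default, which makes
#'   the equal-rate opposing-learning antisymmetry exact; 50 (scale midpoint)
#'   is the usual alternative for sensitivity checks.
#' @param estimate_noise_sd SD (points) of the response noise added to latent
#'   values when simulated agents answer the estimation phase.
#' @return An object of class `"ol_task"`.
#' @examples
#' cfg <- task_config()
#' cfg$upper   # per-option truncation bounds
#' @export
task_config <- function(mu = c(A1 = 64, B = 54, A2 = 64, C = 44),
                        sigma = c(13, 13, 13, 13),
                        min_trials = 100L, max_trials = 300L,
                        stop_tolerance = 1,
                        transfer_repeats = 4L, estimation_repeats = 4L,
                        regime = c("partial", "complete"),
                        q0 = 0, estimate_noise_sd = 5) {
  regime <- match.arg(regime)
  mu <- as.numeric(mu)
  if (length(sigma) == 1L) sigma <- rep(sigma, 4L)
  sigma <- as.numeric(sigma)
  stopifnot(length(mu) == 4L, length(sigma) == 4L, all(sigma > 0),
            min_trials <= max_trials, min_trials >= 1, stop_tolerance > 0,
            transfer_repeats >= 1, estimation_repeats >= 1)
  lower <- pmax(0, mu - 3 * sigma)
  upper <- pmin(100, mu + 3 * sigma)
  if (any(lower >= upper)) stop("degenerate truncation bounds")
  structure(list(
    labels = .STIM,
    mu = setNames(mu, .STIM), sigma = setNames(sigma, .STIM),
    lower = setNames(lower, .STIM), upper = setNames(upper, .STIM),
    min_trials = as.integer(min_trials), max_trials = as.integer(max_trials),
    stop_tolerance = stop_tolerance,
    transfer_repeats = as.integer(transfer_repeats),
    estimation_repeats = as.integer(estimation_repeats),
    regime = regime, q0 = q0, estimate_noise_sd = estimate_noise_sd
  ), class = "ol_task")
}

#' @export
print.ol_task <- function(x, ...) {
  cat("Instrumental learning task (", x$regime, " feedback)\n", sep = "")
  cat(sprintf("  contexts: (A1, B) and (A2, C); rewards N(%g, %g) / N(%g, %g) / N(%g, %g)\n",
              x$mu[1], x$sigma[1], x$mu[2], x$sigma[2], x$mu[4], x$sigma[4]))
  cat(sprintf("  learning: %d-%d trials, stop when |mean(A1)-mean(A2)| < %g\n",
              x$min_trials, x$max_trials, x$stop_tolerance))
  cat(sprintf("  transfer: 6 pairs x %d; estimation: 4 stimuli x %d\n",
              x$transfer_repeats, x$estimation_repeats))
  invisible(x)
}

#' Draw truncated-normal rewards for one option
#'
#' Rejection sampling from N(mu, sigma) conditioned on the option's
#' truncation bounds.  Acceptance rates at the task's +/-3 sigma bounds are
#' ~99.7%, so the loop terminates essentially immediately.
#'
#' @param option stimulus label ("A1", "B", "A2", "C") or index 1..4.
#' @param config an [task_config()] object.
#' @param n number of draws.
#' @return numeric(n) rewards, all within the option's bounds.
#' @examples
#' cfg <- task_config()
#' r <- draw_reward("B", cfg, n = 100)
#' range(r)   # within [15, 93]
#' @export
draw_reward <- function(option, config, n = 1L) {
  i <- if (is.character(option)) .stim_index(option) else as.integer(option)
  stopifnot(length(i) == 1L, i >= 1L, i <= 4L)
  lo <- config$lower[i]; hi <- config$upper[i]
  out <- rnorm(n, config$mu[i], config$sigma[i])
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), config$mu[i], config$sigma[i])
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# internal: vectorized truncated draws for arbitrary mu/sigma/bounds
.draw_trunc <- function(n, mu, sigma, lo, hi) {
  out <- rnorm(n, mu, sigma)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Build the learning-phase schedule
#'
#' The two contexts are pseudorandomly interleaved in consecutive blocks of
#' two trials (one trial per context per block), so context exposure is equal
#' at every even trial count.  Within each context, each stimulus appears on
#' the left in exactly half of that context's scheduled trials.
#'
#' @param config an [task_config()] object.  `max_trials` must be even.
#' @return A data.frame with `max_trials` rows and columns `trial`, `context`
#'   (1 or 2), `stim_left`, `stim_right` (stimulus indices 1..4).
#' @export
build_learning_schedule <- function(config) {
  n <- config$max_trials
  if (n %% 2L != 0L) stop("max_trials must be even for block-interleaving")
  nb <- n %/% 2L
  ctx <- as.vector(apply(matrix(0L, nrow = 2L, ncol = nb), 2L,
                         function(.) sample(1:2)))
  per_ctx <- n %/% 2L
  if (per_ctx %% 2L != 0L) stop("per-context trial count must be even for side counterbalancing")
  sched <- data.frame(trial = seq_len(n), context = ctx,
                      stim_left = integer(n), stim_right = integer(n))
  for (cx in 1:2) {
    idx <- which(ctx == cx)
    pair <- .CONTEXT_PAIR[[cx]]
    # first stimulus of the pair on the left in exactly half the trials
    first_left <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
    sched$stim_left[idx] <- ifelse(first_left, pair[1], pair[2])
    sched$stim_right[idx] <- ifelse(first_left, pair[2], pair[1])
  }
  sched
}

#' Learning-phase stopping decision
#'
#' Implements the adaptive-length rule: continue below `min_trials`; stop once
#' the experienced mean rewards of A1 and A2 differ by less than
#' `stop_tolerance`; flag the run for exclusion if the criterion is still
#' unmet at `max_trials`.
#'
#' @param rewards_a1,rewards_a2 numeric vectors of rewards experienced so far
#'   for A1 and A2.
#' @param trial_index current trial count (>= 1).
#' @param config an [task_config()] object.
#' @return one of `"continue"`, `"stop"`, `"exclude"`.
#' @examples
#' cfg <- task_config()
#' stopping_decision(63.5, 64.3, 100, cfg)  # "stop"
#' @export
stopping_decision <- function(rewards_a1, rewards_a2, trial_index, config) {
  stopifnot(trial_index >= 1)
  if (trial_index < config$min_trials) return("continue")
  if (length(rewards_a1) == 0L || length(rewards_a2) == 0L)
    stop("degenerate history: no experienced rewards for A1 or A2 after min_trials")
  met <- abs(mean(rewards_a1) - mean(rewards_a2)) < config$stop_tolerance
  if (met) return("stop")
  if (trial_index >= config$max_trials) return("exclude")
  "continue"
}

#' Build transfer- and estimation-phase schedules
#'
#' The transfer schedule contains every unordered stimulus pair exactly
#' `transfer_repeats` times in pseudorandom order, with sides counterbalanced
#' within pair; the estimation schedule presents every stimulus
#' `estimation_repeats` times.
#'
#' @param config an [task_config()] object.
#' @return list with data.frames `transfer` (columns `trial`, `stim_left`,
#'   `stim_right`) and `estimation` (columns `trial`, `stim`).
#' @export
build_eval_schedules <- function(config) {
  pairs <- t(utils::combn(4L, 2L))              # 6 unordered pairs
  reps <- config$transfer_repeats
  a <- rep(pairs[, 1], each = reps)
  b <- rep(pairs[, 2], each = reps)
  # counterbalance sides within each pair's repetitions
  flip <- as.vector(vapply(seq_len(nrow(pairs)), function(.)
    sample(rep(c(FALSE, TRUE), length.out = reps)), logical(reps)))
  left <- ifelse(flip, b, a)
  right <- ifelse(flip, a, b)
  ord <- sample.int(length(left))
  transfer <- data.frame(trial = seq_along(ord),
                         stim_left = left[ord], stim_right = right[ord])
  est <- sample(rep(1:4, config$estimation_repeats))
  estimation <- data.frame(trial = seq_along(est), stim = est)
  list(transfer = transfer, estimation = estimation)
}

#' Read / write a task configuration file
#'
#' Plain-text YAML mapping with one key per line (means, sigmas, trial
#' bounds, tolerance, feedback regime, ...).
#'
#' @param path file path.
#' @param config an [task_config()] object.
#' @return `read_task_config()` returns an `"ol_task"` object.
#' @examples
#' cfg <- read_task_config(system.file("extdata", "normalized_task.yml",
#'                                     package = "oppolearn"))
#' cfg$mu
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(task_config)))]
  do.call(task_config, args)
}

#' @rdname read_task_config
#' @export
write_task_config <- function(config, path) {
  y <- list(mu = as.numeric(config$mu), sigma = as.numeric(config$sigma),
            min_trials = config$min_trials, max_trials = config$max_trials,
            stop_tolerance = config$stop_tolerance,
            transfer_repeats = config$transfer_repeats,
            estimation_repeats = config$estimation_repeats,
            regime = config$regime, q0 = config$q0,
            estimate_noise_sd = config$estimate_noise_sd)
  yaml::write_yaml(y, path)
  invisible(path)
}
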