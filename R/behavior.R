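#' Learning / transfer performance
#'
#' Fraction of answered trials on which the higher-mean option of the
#' displayed pair was chosen, plus per-context learning curves binned in
#' blocks of `bin` trials.  "Advantageous" is defined by the generating
#' means in `config` (A1 over B, A2 over C; across contexts by mean rank).
#'
#' @param data behavioral dataset.
#' @param phase `"learning"` or `"transfer"`.
#' @param config an [task_config()] supplying the option means.
#' @param bin learning-curve bin width (trials).
#' @return list with `fraction` (overall, pooled across subjects),
#'   `per_subject`, and (learning phase) `curves`, a data.frame of binned
#'   per-context accuracies.
#' @export
performance <- function(data, phase = c("learning", "transfer"),
                        config = task_config(), bin = 10L) {
  phase <- match.arg(phase)
  d <- data[data$phase == phase & !is.na(data$choice), ]
  if (!nrow(d)) stop("no answered ", phase, " trials")
  mu <- config$mu
  lf <- mu[d$stim_left]; rt <- mu[d$stim_right]
  # pairs with equal means (A1 vs A2) carry no accuracy information
  informative <- lf != rt
  adv <- ifelse(lf > rt, d$stim_left, d$stim_right)
  correct <- as.numeric(d$choice == adv)[informative]
  subj <- d$subject[informative]
  per_subject <- tapply(correct, subj, mean)
  out <- list(fraction = mean(correct),
              per_subject = data.frame(subject = names(per_subject),
                                       accuracy = as.numeric(per_subject),
                                       row.names = NULL))
  if (phase == "learning") out$curves <- .binned_curves(data, bin)
  out
}

#' Transfer bias toward the option learned in the poorer context
#'
#' A1 and A2 pay identically, but A2 was learned against the worse partner
#' (C); a preference for A2 on (A1, A2) transfer trials is the signature of
#' context-dependent valuation.  The test counts, per subject, the first
#' (A1, A2) transfer trial and compares the fraction of subjects choosing
#' A2 against 0.5 with an exact binomial test (one-sided toward A2 by
#' default).  Per-subject A2-choice rates over all (A1, A2) repetitions are
#' returned for location tests.
#'
#' @param data behavioral dataset (cohort).
#' @param alternative passed to [stats::binom.test()]; default `"greater"`.
#' @return list with `n` (subjects with an (A1, A2) trial), `n_chose_a2`,
#'   `ratio`, `p_value`, `per_subject_rate` (all-iteration A2 rates), and
#'   `excluded` (subjects without an answered (A1, A2) trial).
#' @examples
#' \donttest{
#' cfg <- task_config()
#' d <- simulate_cohort("OL1", 20, cfg, seed = 3)
#' transfer_bias_test(d)$ratio
#' }
#' @export
transfer_bias_test <- function(data, alternative = c("greater", "two.sided",
                                                     "less")) {
  alternative <- match.arg(alternative)
  d <- data[data$phase == "transfer" & !is.na(data$choice), ]
  pair <- (d$stim_left == "A1" & d$stim_right == "A2") |
    (d$stim_left == "A2" & d$stim_right == "A1")
  d <- d[pair, ]
  subs <- unique(data$subject)
  first_a2 <- logical(0); rates <- numeric(0); kept <- character(0)
  excluded <- character(0)
  for (sj in subs) {
    ds <- d[d$subject == sj, ]
    if (!nrow(ds)) { excluded <- c(excluded, sj); next }
    ds <- ds[order(ds$trial), ]
    kept <- c(kept, sj)
    first_a2 <- c(first_a2, ds$choice[1] == "A2")
    rates <- c(rates, mean(ds$choice == "A2"))
  }
  if (!length(kept)) stop("no subject has an answered (A1, A2) transfer trial")
  bt <- binom.test(sum(first_a2), length(first_a2), p = 0.5,
                   alternative = alternative)
  list(n = length(kept), n_chose_a2 = sum(first_a2),
       ratio = mean(first_a2), p_value = bt$p.value,
       per_subject_rate = data.frame(subject = kept, a2_rate = rates,
                                     row.names = NULL),
       excluded = excluded)
}

#' Confound features for the transfer bias
#'
#' Candidate non-contextual explanations of an A2 preference: unequal
#' choice frequency during learning, or unusually extreme rewards.  For one
#' subject, returns per-arm choice counts, the A2 - A1 count difference,
#' and per-arm sums of observed rewards beyond mu +/- 2.5 sigma of the
#' arm's generating distribution.
#'
#' @param data behavioral dataset.
#' @param subject subject id (may be omitted for single-subject data).
#' @param config an [task_config()] supplying mu and sigma per arm.
#' @param last_n if given, restrict to the last `last_n` learning trials.
#' @return one-row data.frame with columns `subject`, `n_A1`, `n_A2`,
#'   `freq_diff` (A2 - A1), and `high_sum_A1`, `high_sum_A2`, `low_sum_A1`,
#'   `low_sum_A2` (sums of rewards above mu + 2.5 sigma / below
#'   mu - 2.5 sigma).
#' @export
confound_features <- function(data, subject = NULL, config = task_config(),
                              last_n = NULL) {
  subject <- .one_subject(data, subject)
  d <- data[data$subject == subject & data$phase == "learning" &
              !is.na(data$choice), ]
  if (!nrow(d)) stop("no learning phase for subject ", subject)
  if (!is.null(last_n)) d <- d[d$trial > max(d$trial) - last_n, ]
  feat <- function(arm) {
    rew <- d$r_chosen[d$choice == arm]
    hi <- config$mu[arm] + 2.5 * config$sigma[arm]
    lo <- config$mu[arm] - 2.5 * config$sigma[arm]
    c(n = length(rew), high = sum(rew[rew > hi]), low = sum(rew[rew < lo]))
  }
  a1 <- feat("A1"); a2 <- feat("A2")
  data.frame(subject = subject, n_A1 = a1[["n"]], n_A2 = a2[["n"]],
             freq_diff = a2[["n"]] - a1[["n"]],
             high_sum_A1 = a1[["high"]], high_sum_A2 = a2[["high"]],
             low_sum_A1 = a1[["low"]], low_sum_A2 = a2[["low"]])
}

#' Logistic check of a confound against the transfer bias
#'
#' Maximum-likelihood logistic regression of the per-subject A2-preference
#' indicator on a single candidate confound (intercept + slope), as used to
#' rule out choice-frequency and extreme-reward explanations: a significant
#' intercept with a null slope indicates a bias not carried by the
#' confound.
#'
#' @param chose_a2 logical/0-1 vector, one entry per subject (first
#'   (A1, A2) iteration or all-iteration rate).
#' @param predictor numeric confound feature, same length.
#' @return data.frame with rows `(Intercept)` and `predictor`: estimates,
#'   standard errors, z statistics and p-values.
#' @export
bias_logistic <- function(chose_a2, predictor) {
  stopifnot(length(chose_a2) == length(predictor))
  fit <- glm(chose_a2 ~ predictor, family = binomial())
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             z = sm[, 3], p_value = sm[, 4], row.names = NULL)
}

#' Cohort summary
#'
#' Convenience wrapper bundling [performance()], [transfer_bias_test()] and
#' per-subject [confound_features()] for a whole cohort.
#'
#' @param data behavioral dataset.
#' @param config an [task_config()].
#' @return list with `learning`, `transfer`, `bias`, `confounds`.
#' @export
cohort_summary <- function(data, config = task_config()) {
  subs <- unique(data$subject)
  conf <- do.call(rbind, lapply(subs, function(sj)
    confound_features(data, sj, config)))
  list(learning = performance(data, "learning", config),
       transfer = performance(data, "transfer", config),
       bias = transfer_bias_test(data),
       confounds = conf)
}
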