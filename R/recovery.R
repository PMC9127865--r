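#' Bayes inversion of a model-recovery confusion matrix
#'
#' Converts winner frequencies `p(fit | gen)` into the posterior over
#' generating models `p(gen | fit)` under a uniform prior over models:
#' column `f` of the result is `p(fit=f | gen) / sum_g p(fit=f | gen=g)`.
#'
#' @param p_fit_given_gen square matrix, rows = generating model, columns =
#'   best-fitting model; each row sums to 1.
#' @return matrix of the same shape; every column with non-zero evidence
#'   sums to 1.
#' @export
p_gen_given_fit <- function(p_fit_given_gen) {
  m <- as.matrix(p_fit_given_gen)
  stopifnot(nrow(m) == ncol(m))
  cs <- colSums(m)
  out <- sweep(m, 2, ifelse(cs > 0, cs, NA_real_), `/`)
  dimnames(out) <- dimnames(m)
  out
}

#' Parameter-recovery study
#'
#' Samples synthetic subjects from per-parameter Beta generating
#' distributions, simulates them on the task, refits the same model by MAP,
#' and summarizes recovery per parameter: the Pearson correlation between
#' true and recovered values and the regression
#' `recovered = b0 + b1 * true`.
#'
#' @param model model key.
#' @param config an [task_config()]; its `regime` selects the model variant.
#' @param n_subjects synthetic subjects per repetition.
#' @param repetitions independent repetitions (cohorts).
#' @param moments generating moments (`data.frame` with `param`, `mean`,
#'   `sd`) or a sampler function; defaults to [default_param_moments()].
#' @param n_restarts optimizer restarts per fit.
#' @param seed integer seed.
#' @return An object of class `"recovery_report"` with elements `true` and
#'   `recovered` (subjects x parameters), `correlations`, and `regressions`
#'   (per-parameter `b0`, `b1` with standard errors and p-values).  A
#'   parameter held constant across the cohort has `NA` correlation.
#' @export
parameter_recovery_study <- function(model, config, n_subjects = 30L,
                                     repetitions = 1L, moments = NULL,
                                     n_restarts = 10L, seed = 1L) {
  if (is.null(moments))
    moments <- default_param_moments(model, config$regime)
  info <- .model_info(model, config$regime)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, 2L * repetitions)
  true_l <- list(); rec_l <- list()
  for (r in seq_len(repetitions)) {
    cohort <- simulate_cohort(model, n_subjects, config,
                              seed = rep_seeds[2L * r - 1L],
                              sampler = moments)
    meta <- attr(cohort, "meta")
    true <- do.call(rbind, lapply(meta, function(m)
      unlist(m$params)[info$par_names]))
    fit <- rl_fit(cohort, model, n_restarts = n_restarts,
                  seed = rep_seeds[2L * r], q0 = config$q0)
    true_l[[r]] <- true
    rec_l[[r]] <- coef(fit)
  }
  true <- do.call(rbind, true_l)
  rec <- do.call(rbind, rec_l)
  cors <- vapply(info$par_names, function(pn) {
    if (sd(true[, pn]) == 0 || sd(rec[, pn]) == 0) return(NA_real_)
    cor(true[, pn], rec[, pn])
  }, numeric(1))
  regs <- lapply(info$par_names, function(pn) {
    if (sd(true[, pn]) == 0)
      return(data.frame(param = pn, b0 = NA, b0_se = NA, b1 = NA,
                        b1_se = NA, p_value = NA))
    sm <- summary(lm(rec[, pn] ~ true[, pn]))$coefficients
    data.frame(param = pn, b0 = sm[1, 1], b0_se = sm[1, 2],
               b1 = sm[2, 1], b1_se = sm[2, 2], p_value = sm[2, 4])
  })
  structure(list(kind = "parameter", model = model,
                 regime = config$regime, true = true, recovered = rec,
                 correlations = cors,
                 regressions = do.call(rbind, regs)),
            class = "recovery_report")
}

#' Model-recovery study
#'
#' For every generating model, simulates cohorts with parameters drawn from
#' that model's generating distributions, fits every candidate model to
#' every synthetic subject, and selects per-subject winners by AIC.  Winner
#' frequencies give the confusion matrix `p(fit | gen)`; [p_gen_given_fit()]
#' inverts it under a uniform prior over models.
#'
#' @param models character vector of candidate model keys (all fittable in
#'   `config$regime`).
#' @param config an [task_config()].
#' @param n_subjects subjects per repetition; @param repetitions cohorts per
#'   generating model.
#' @param moments named list of generating moments per model (defaults to
#'   each model's [default_param_moments()]).
#' @param n_restarts optimizer restarts per fit.
#' @param seed integer seed.
#' @param max_fail_frac abort if more than this fraction of fits fail.
#' @return An object of class `"recovery_report"` with `p_fit_given_gen`,
#'   `p_gen_given_fit`, raw winner `counts`, and `failures`.
#' @export
model_recovery_study <- function(models, config, n_subjects = 10L,
                                 repetitions = 5L, moments = NULL,
                                 n_restarts = 3L, seed = 1L,
                                 max_fail_frac = 0.05) {
  for (m in models) .model_info(m, config$regime)   # validate keys early
  M <- length(models)
  counts <- matrix(0L, M, M, dimnames = list(gen = models, fit = models))
  failures <- 0L; total <- 0L
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             M * repetitions * (M + 1L)),
                  nrow = M * repetitions)
  row_i <- 0L
  for (gi in seq_along(models)) {
    gmod <- models[gi]
    mom <- if (!is.null(moments)) moments[[gmod]] else
      default_param_moments(gmod, config$regime)
    for (r in seq_len(repetitions)) {
      row_i <- row_i + 1L
      cohort <- simulate_cohort(gmod, n_subjects, config,
                                seed = seeds[row_i, 1L], sampler = mom)
      sub_ids <- unique(cohort$subject)
      aics <- matrix(NA_real_, n_subjects, M)
      for (fi in seq_along(models)) {
        fit <- tryCatch(
          rl_fit(cohort, models[fi], n_restarts = n_restarts,
                 seed = seeds[row_i, fi + 1L], q0 = config$q0),
          error = function(e) NULL)
        total <- total + n_subjects
        if (is.null(fit)) { failures <- failures + n_subjects; next }
        aics[, fi] <- fit$fits$aic[match(sub_ids, fit$fits$subject)]
      }
      if (failures / total > max_fail_frac)
        stop("fit failure rate exceeded ", max_fail_frac)
      ok <- rowSums(is.na(aics)) == 0L
      if (any(ok)) {
        win <- apply(aics[ok, , drop = FALSE], 1, which.min)
        for (wv in win) counts[gi, wv] <- counts[gi, wv] + 1L
      }
    }
  }
  pfg <- counts / pmax(rowSums(counts), 1L)
  structure(list(kind = "model", models = models, regime = config$regime,
                 counts = counts, p_fit_given_gen = pfg,
                 p_gen_given_fit = p_gen_given_fit(pfg),
                 failures = failures, total_fits = total),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (x$kind == "parameter") {
    cat("Parameter recovery:", x$model, "(", x$regime, "feedback ),",
        nrow(x$true), "synthetic subjects\n\n")
    cat("Pearson correlation (true vs recovered):\n")
    print(round(x$correlations, 3))
    cat("\nRegression recovered = b0 + b1 * true:\n")
    print(x$regressions, digits = 3, row.names = FALSE)
  } else {
    cat("Model recovery (", x$regime, " feedback ), winners by AIC\n",
        sep = "")
    cat("\np(fit | gen):\n"); print(round(x$p_fit_given_gen, 3))
    cat("\np(gen | fit):\n"); print(round(x$p_gen_given_fit, 3))
    if (x$failures > 0)
      cat("\n", x$failures, "of", x$total_fits, "fits failed\n")
  }
  invisible(x)
}
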