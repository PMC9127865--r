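#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies `r` follow a Dirichlet prior (concentration
#' `prior_alpha` per model, default uniform) and each subject's model
#' assignment is multinomial in `r`.  The posterior over `r` is obtained
#' with the standard variational scheme; the exceedance probability (xp) of
#' a model is the posterior probability that it is the most frequent model
#' in the population, and the protected exceedance probability (pxp) blends
#' xp with chance according to the Bayes omnibus risk (bor), the posterior
#' probability that model frequencies are all equal and observed differences
#' arose by chance.
#'
#' BIC-based log evidence is the usual input here (`-bic/2`); with subjects
#' differing in trial counts the BIC penalty adapts per subject.
#'
#' @param log_evidence numeric subjects x models matrix of log model
#'   evidences (e.g., `-bic/2`), with model names as column names.
#' @param prior_alpha prior Dirichlet concentration per model.
#' @param n_samples Monte-Carlo draws for the exceedance probabilities when
#'   more than two models are compared (the two-model case is computed
#'   analytically from the Beta posterior).
#' @param seed integer seed for the Monte-Carlo step.
#' @param tol,max_iter convergence control of the variational loop.
#' @return An object of class `"bms"`: list with `alpha` (posterior
#'   concentrations), `expected_freq`, `xp`, `pxp`, `bor`, `g` (posterior
#'   model responsibilities per subject), `F1`, `F0`.
#' @examples
#' ev <- cbind(m1 = c(-100, -102, -101), m2 = c(-104, -103, -105))
#' random_effects_bms(ev, seed = 1)
#' @export
random_effects_bms <- function(log_evidence, prior_alpha = 1,
                               n_samples = 1e6, seed = NULL,
                               tol = 1e-8, max_iter = 500L) {
  le <- as.matrix(log_evidence)
  if (ncol(le) < 2L) stop("need at least two models")
  if (nrow(le) < 1L) stop("need at least one subject")
  if (any(!is.finite(le))) {
    bad <- which(!is.finite(le), arr.ind = TRUE)[1, ]
    stop("non-finite log evidence for subject ", bad[1], ", model ",
         colnames(le)[bad[2]] %||% bad[2])
  }
  M <- ncol(le); N <- nrow(le)
  a0 <- rep(prior_alpha, M)
  alpha <- a0 + N / M
  for (it in seq_len(max_iter)) {
    lg <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg); g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- .dirichlet_exceedance(alpha, n_samples, seed)
  # free energy of the random-effects model vs the equal-frequency null
  elnr <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(g * le) + sum((a0 - alpha + colSums(g)) * elnr) +
    lgamma(sum(a0)) - sum(lgamma(a0)) - lgamma(sum(alpha)) +
    sum(lgamma(alpha)) - sum(g[g > 0] * log(g[g > 0]))
  F0 <- sum(apply(le, 1, function(r) {
    m <- max(r); m + log(mean(exp(r - m)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- (1 - bor) * xp + bor / M
  structure(list(alpha = setNames(alpha, colnames(le)),
                 expected_freq = setNames(alpha / sum(alpha), colnames(le)),
                 xp = setNames(xp, colnames(le)),
                 pxp = setNames(pxp, colnames(le)),
                 bor = bor, g = g, F1 = F1, F0 = F0, iterations = it),
            class = "bms")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# P(r_m is the largest frequency) under Dirichlet(alpha)
.dirichlet_exceedance <- function(alpha, n_samples = 1e6, seed = NULL) {
  M <- length(alpha)
  if (M == 2L)
    return(c(1 - pbeta(0.5, alpha[1], alpha[2]),
             pbeta(0.5, alpha[1], alpha[2])))
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(M)
  chunk <- 1e5L
  done <- 0L
  while (done < n_samples) {
    n <- min(chunk, as.integer(n_samples - done))
    x <- matrix(rgamma(n * M, shape = rep(alpha, each = n)), nrow = n)
    counts <- counts + tabulate(max.col(x), nbins = M)
    done <- done + n
  }
  counts / done
}

#' @export
print.bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection (", length(x$alpha),
      " models, ", round(sum(x$alpha) - length(x$alpha)),
      " subjects)\n", sep = "")
  tab <- data.frame(model = names(x$alpha),
                    expected_freq = round(x$expected_freq, 4),
                    xp = round(x$xp, 5), pxp = round(x$pxp, 5),
                    row.names = NULL)
  print(tab)
  cat(sprintf("Bayes omnibus risk: %.4g\n", x$bor))
  invisible(x)
}
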