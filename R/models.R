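#' Softmax probability of choosing one option over another
#'
#' `p = 1 / (1 + exp(beta * (q_un - q_ch)))`, computed in a numerically
#' stable form.  `beta` is the inverse temperature: 0 gives random choice,
#' large values approach greedy choice.
#'
#' @param q_ch,q_un values of the chosen and unchosen option.
#' @param beta inverse temperature (>= 0).
#' @return probability in (0, 1); the probabilities of the two options sum
#'   to 1.
#' @examples
#' softmax_choice_prob(15, 5, 0.1)  # 1 / (1 + exp(-1))
#' @export
softmax_choice_prob <- function(q_ch, q_un, beta) {
  stopifnot(all(beta >= 0))
  x <- beta * (q_ch - q_un)
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

# stable log(softmax_choice_prob)
.log_softmax_prob <- function(q_ch, q_un, beta) {
  x <- beta * (q_ch - q_un)
  ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
}

#' Hybrid regret/relief reward
#'
#' Weighted mix of the absolute strategy (maximize the factual outcome) and
#' the relative strategy (maximize the outcome difference, i.e., minimize
#' regret): `r_hyb = w * r_fc + (1 - w) * (r_fc - counterfactual)`.
#' Under complete feedback the counterfactual is the forgone option's shown
#' outcome; under partial feedback the learned value of the unchosen option
#' stands in for it.
#'
#' @param r_fc factual (chosen) outcome, points.
#' @param counterfactual forgone outcome (complete feedback) or the unchosen
#'   option's current value (partial feedback).
#' @param w weight of the absolute strategy in \[0, 1\].
#' @return hybrid reward, points.
#' @examples
#' hybrid_reward(64, 54, 0.5)  # 37
#' @export
hybrid_reward <- function(r_fc, counterfactual, w) {
  stopifnot(all(w >= 0 & w <= 1))
  w * r_fc + (1 - w) * (r_fc - counterfactual)
}

#' Initial agent state
#'
#' All option values (and context values) start at `q0`; experience weights
#' start at 1; sample histories start empty.
#'
#' @param q0 initial value (points).
#' @return list with elements `q` (stimulus values), `v` (context values),
#'   `n` (experience weights), `hist_r`/`hist_t` (per-stimulus reward
#'   histories with trial indices), `t` (trial counter).
#' @export
init_state <- function(q0 = 0) {
  list(q = setNames(rep(q0, 4), .STIM), v = c(q0, q0),
       n = setNames(rep(1, 4), .STIM),
       hist_r = rep(list(numeric(0)), 4), hist_t = rep(list(integer(0)), 4),
       t = 0L, q0 = q0)
}

# feedback constructor used internally and by tests
.feedback <- function(chosen, unchosen, r_chosen, r_unchosen = NA_real_) {
  ch <- if (is.character(chosen)) .stim_index(chosen) else as.integer(chosen)
  un <- if (is.character(unchosen)) .stim_index(unchosen) else as.integer(unchosen)
  if (.CONTEXT_OF[ch] != .CONTEXT_OF[un])
    stop("chosen and unchosen stimuli must belong to the same context")
  list(chosen = ch, unchosen = un, context = .CONTEXT_OF[ch],
       r_chosen = r_chosen, r_unchosen = r_unchosen)
}

.need_run <- function(feedback, regime) {
  if (regime == "complete" && is.na(feedback$r_unchosen))
    stop("complete feedback requires the unchosen outcome")
}

#' Per-trial update rules of the model families
#'
#' Each `*_step()` function applies one trial's value update and returns the
#' new state; only the two stimuli of the current context are touched.  These
#' are the reference R implementations of the rules; the fitting routines use
#' a compiled replay of the same rules.
#'
#' * `sql_step()`: standard Q-learning.  The chosen value moves toward its
#'   own outcome, `Q_ch <- Q_ch + alpha1 * (r_ch - Q_ch)`; with
#'   `extended = TRUE` (complete feedback only) the unchosen value is updated
#'   with its own outcome at rate `alpha2`.
#' * `rp_step()`: reference-point learning.  A context value `V` tracks a
#'   contextual reward (variant `"RPD"`: the chosen outcome; `"RPA"`: the
#'   average of the two outcomes, with `Q_un` standing in for the forgone
#'   outcome under partial feedback; `"RPM"`: their max) at rate `alpha1`;
#'   option values then learn outcomes re-expressed relative to the updated
#'   `V` at rate `alpha2` (and `alpha3` for the unchosen option under
#'   complete feedback).
#' * `dif_step()`: relative-value learning of the outcome difference
#'   `r_fc - r_cf` (complete feedback only).
#' * `hyb_step()`: Q-learning on the [hybrid_reward()]; `w = 1` reduces to
#'   `sql_step()` and `w = 0` (complete) to `dif_step()`.
#' * `fql_step()`: forgetting Q-learning; the chosen value learns as in SQL
#'   while the unchosen value decays, `Q_un <- alpha2 * Q_un`.
#' * `ewa_step()`: experience-weighted attraction with per-stimulus
#'   experience weights `N` (decay `rho`), value decay `phi`, and
#'   counterfactual weight `delta_imit` (complete feedback only).
#' * `relasym_step()`: reference-point stage (average contextual reward, as
#'   in `"RPA"`) followed by asymmetric (confirmation-bias) updating: the
#'   chosen value learns positive prediction errors at `alpha_conf` and
#'   negative ones at `alpha_disc`; for the unchosen option the sign
#'   condition is flipped.
#' * `ol_step()`: opposing learning.  The *chosen* prediction error updates
#'   both values in opposite directions: `Q_ch <- Q_ch + alpha1 * d` and
#'   `Q_un <- Q_un - alpha2 * d`.  Under complete feedback the prediction
#'   error is taken on the [hybrid_reward()] (`d = r_hyb - Q_ch`).
#'
#' @param state agent state from [init_state()].
#' @param feedback list with elements `chosen`, `unchosen` (labels or indices
#'   1..4), `r_chosen`, and `r_unchosen` (NA under partial feedback).
#' @param params named numeric vector of model parameters (see
#'   [model_registry()] for each model's parameter set).
#' @param regime `"partial"` or `"complete"`.
#' @param extended for `sql_step()`: also update the unchosen value with its
#'   own outcome (requires complete feedback).
#' @param variant for `rp_step()`: `"RPD"`, `"RPA"` or `"RPM"`.
#' @param ref for `relasym_step()`: contextual-reward definition for the
#'   reference stage (default `"average"`).
#' @return the updated state.
#' @examples
#' st <- init_state()
#' st$q["A1"] <- 50
#' fb <- list(chosen = "A1", unchosen = "B", r_chosen = 64)
#' sql_step(st, fb, c(beta = 0.1, alpha1 = 0.25), "partial")$q["A1"]  # 53.5
#' @name model_steps
NULL

.as_feedback <- function(feedback) {
  if (is.character(feedback$chosen) || is.character(feedback$unchosen))
    feedback <- .feedback(feedback$chosen, feedback$unchosen,
                          feedback$r_chosen,
                          if (is.null(feedback$r_unchosen)) NA_real_ else feedback$r_unchosen)
  if (is.null(feedback$r_unchosen)) feedback$r_unchosen <- NA_real_
  if (is.null(feedback$context)) feedback$context <- .CONTEXT_OF[feedback$chosen]
  feedback
}

#' @rdname model_steps
#' @export
sql_step <- function(state, feedback, params, regime = "partial",
                     extended = FALSE) {
  fb <- .as_feedback(feedback)
  if (extended && regime != "complete")
    stop("extended SQL requires complete feedback")
  state$q[fb$chosen] <- state$q[fb$chosen] +
    params[["alpha1"]] * (fb$r_chosen - state$q[fb$chosen])
  if (extended) {
    .need_run(fb, regime)
    state$q[fb$unchosen] <- state$q[fb$unchosen] +
      params[["alpha2"]] * (fb$r_unchosen - state$q[fb$unchosen])
  }
  state
}

#' @rdname model_steps
#' @export
rp_step <- function(state, feedback, params, regime = "partial",
                    variant = c("RPD", "RPA", "RPM")) {
  variant <- match.arg(variant)
  fb <- .as_feedback(feedback)
  if (regime == "complete") .need_run(fb, regime)
  qun <- state$q[fb$unchosen]
  rx <- switch(variant,
    RPD = fb$r_chosen,
    RPA = if (regime == "complete") (fb$r_chosen + fb$r_unchosen) / 2
          else (fb$r_chosen + qun) / 2,
    RPM = if (regime == "complete") max(fb$r_chosen, fb$r_unchosen)
          else max(fb$r_chosen, qun))
  cx <- fb$context
  state$v[cx] <- state$v[cx] + params[["alpha1"]] * (rx - state$v[cx])
  # the chosen-option prediction error uses the freshly updated context value
  state$q[fb$chosen] <- state$q[fb$chosen] +
    params[["alpha2"]] * ((fb$r_chosen - state$v[cx]) - state$q[fb$chosen])
  if (regime == "complete")
    state$q[fb$unchosen] <- state$q[fb$unchosen] +
      params[["alpha3"]] * ((fb$r_unchosen - state$v[cx]) - state$q[fb$unchosen])
  state
}

#' @rdname model_steps
#' @export
dif_step <- function(state, feedback, params, regime = "complete") {
  if (regime != "complete") stop("the difference model requires complete feedback")
  fb <- .as_feedback(feedback)
  .need_run(fb, regime)
  r_rlt <- fb$r_chosen - fb$r_unchosen
  state$q[fb$chosen] <- state$q[fb$chosen] +
    params[["alpha1"]] * (r_rlt - state$q[fb$chosen])
  state
}

#' @rdname model_steps
#' @export
hyb_step <- function(state, feedback, params, regime = "partial") {
  fb <- .as_feedback(feedback)
  cf <- if (regime == "complete") {
    .need_run(fb, regime); fb$r_unchosen
  } else state$q[fb$unchosen]
  rhyb <- hybrid_reward(fb$r_chosen, cf, params[["w"]])
  state$q[fb$chosen] <- state$q[fb$chosen] +
    params[["alpha1"]] * (rhyb - state$q[fb$chosen])
  state
}

#' @rdname model_steps
#' @export
fql_step <- function(state, feedback, params, regime = "partial") {
  fb <- .as_feedback(feedback)
  state$q[fb$chosen] <- state$q[fb$chosen] +
    params[["alpha1"]] * (fb$r_chosen - state$q[fb$chosen])
  state$q[fb$unchosen] <- params[["alpha2"]] * state$q[fb$unchosen]
  state
}

#' @rdname model_steps
#' @export
ewa_step <- function(state, feedback, params, regime = "partial") {
  fb <- .as_feedback(feedback)
  rho <- params[["rho"]]; phi <- params[["phi"]]
  ch <- fb$chosen
  n_old <- state$n[ch]; n_new <- rho * n_old + 1
  state$q[ch] <- (state$q[ch] * n_old * phi + fb$r_chosen) / n_new
  state$n[ch] <- n_new
  if (regime == "complete") {
    .need_run(fb, regime)
    un <- fb$unchosen
    m_old <- state$n[un]; m_new <- rho * m_old + 1
    state$q[un] <- (state$q[un] * m_old * phi +
                      params[["delta_imit"]] * fb$r_unchosen) / m_new
    state$n[un] <- m_new
  }
  state
}

#' @rdname model_steps
#' @export
relasym_step <- function(state, feedback, params, regime = "partial",
                         ref = c("average", "direct", "max")) {
  ref <- match.arg(ref)
  fb <- .as_feedback(feedback)
  if (regime == "complete") .need_run(fb, regime)
  qun <- state$q[fb$unchosen]
  other <- if (regime == "complete") fb$r_unchosen else qun
  rx <- switch(ref, average = (fb$r_chosen + other) / 2,
               direct = fb$r_chosen, max = max(fb$r_chosen, other))
  cx <- fb$context
  state$v[cx] <- state$v[cx] + params[["alpha1"]] * (rx - state$v[cx])
  dch <- (fb$r_chosen - state$v[cx]) - state$q[fb$chosen]
  rate_ch <- if (dch > 0) params[["alpha_conf"]] else params[["alpha_disc"]]
  state$q[fb$chosen] <- state$q[fb$chosen] + rate_ch * dch
  if (regime == "complete") {
    dun <- (fb$r_unchosen - state$v[cx]) - state$q[fb$unchosen]
    # sign condition deliberately flipped for the unchosen option
    rate_un <- if (dun < 0) params[["alpha_conf"]] else params[["alpha_disc"]]
    state$q[fb$unchosen] <- state$q[fb$unchosen] + rate_un * dun
  }
  state
}

#' @rdname model_steps
#' @export
ol_step <- function(state, feedback, params, regime = "partial") {
  fb <- .as_feedback(feedback)
  a1 <- params[["alpha1"]]
  a2 <- if ("alpha2" %in% names(params)) params[["alpha2"]] else a1
  d <- if (regime == "complete") {
    .need_run(fb, regime)
    w <- if ("w" %in% names(params)) params[["w"]] else 1
    hybrid_reward(fb$r_chosen, fb$r_unchosen, w) - state$q[fb$chosen]
  } else fb$r_chosen - state$q[fb$chosen]
  state$q[fb$chosen] <- state$q[fb$chosen] + a1 * d
  state$q[fb$unchosen] <- state$q[fb$unchosen] - a2 * d
  state
}

#' Trial likelihood of the sample-based episodic model
#'
#' The sample-based episodic learner estimates each option's value by
#' recency-weighted sampling of its past outcomes: sample `r_i` from trial
#' `i` is drawn with weight `alpha * (1 - alpha)^(t - i)`.  The probability
#' of the observed choice is the mixture, over all pairs of sampled values,
#' of the softmax choice probability.  Weights are renormalized per option so
#' the mixture is a proper distribution (`normalize = FALSE` gives the raw
#' printed weights); an option with no samples yet contributes a single
#' pseudo-sample at the initial value `q0` with probability 1.
#'
#' @param hist_r_ch,hist_t_ch chosen option's past rewards and their trial
#'   indices.
#' @param hist_r_un,hist_t_un same for the unchosen option.
#' @param t current trial index (later than all history indices).
#' @param alpha recency rate in (0, 1\].
#' @param beta softmax inverse temperature.
#' @param q0 initial value used for the empty-history pseudo-sample.
#' @param normalize renormalize the recency weights per option (default).
#' @return probability of choosing the chosen option, in (0, 1).
#' @export
sbe_trial_likelihood <- function(hist_r_ch, hist_t_ch, hist_r_un, hist_t_un,
                                 t, alpha, beta, q0 = 0, normalize = TRUE) {
  stopifnot(alpha > 0, alpha <= 1)
  if ((length(hist_t_ch) && t <= max(hist_t_ch)) ||
      (length(hist_t_un) && t <= max(hist_t_un)))
    stop("current trial index must be later than all history entries")
  wv <- function(r, ti) {
    if (length(r) == 0L) return(list(v = q0, w = 1))
    w <- alpha * (1 - alpha)^(t - ti)
    if (normalize) w <- w / sum(w)
    list(v = r, w = w)
  }
  ch <- wv(hist_r_ch, hist_t_ch); un <- wv(hist_r_un, hist_t_un)
  p <- outer(ch$v, un$v, function(a, b) softmax_choice_prob(a, b, beta))
  sum((ch$w %o% un$w) * p)
}

# ---------------------------------------------------------------------------
# model registry

.MODEL_IDS <- c(SQL = 1L, SQL2 = 2L, RPD = 3L, RPA = 4L, RPM = 5L, Dif = 6L,
                Hyb = 7L, FQL = 8L, EWA = 9L, SBE = 10L, RelAsym = 11L,
                OL1 = 12L, OL2 = 13L)

#' Registry of model families
#'
#' Models are keyed by family name and feedback regime.  Each entry lists the
#' free parameters in the order expected by the fitting routines (all
#' parameters live in \[0, 1\]; the inverse temperature is bounded to \[0, 1\]
#' during fitting because option values are on a 0--100 point scale).
#'
#' Available keys: `SQL` (standard Q-learning), `SQL2` (extended SQL,
#' complete feedback only), `RPD`/`RPA`/`RPM` (reference-point variants),
#' `Dif` (difference model, complete only), `Hyb` (hybrid regret/relief),
#' `FQL` (forgetting Q-learning), `EWA` (experience-weighted attraction),
#' `SBE` (sample-based episodic), `RelAsym` (relative asymmetric), `OL1`
#' (opposing learning, equal rates), `OL2` (opposing learning, distinct
#' rates, constrained `alpha2 <= alpha1`).
#'
#' @param regime `"partial"` or `"complete"`; `model_registry(NULL)` lists
#'   all keys.
#' @return named list of model descriptors (`par_names`, `k`, `id`, ...).
#' @export
model_registry <- function(regime = NULL) {
  base <- list(
    SQL = list(partial = c("beta", "alpha1"), complete = c("beta", "alpha1")),
    SQL2 = list(complete = c("beta", "alpha1", "alpha2")),
    RPD = list(partial = c("beta", "alpha1", "alpha2"),
               complete = c("beta", "alpha1", "alpha2", "alpha3")),
    RPA = list(partial = c("beta", "alpha1", "alpha2"),
               complete = c("beta", "alpha1", "alpha2", "alpha3")),
    RPM = list(partial = c("beta", "alpha1", "alpha2"),
               complete = c("beta", "alpha1", "alpha2", "alpha3")),
    Dif = list(complete = c("beta", "alpha1")),
    Hyb = list(partial = c("beta", "alpha1", "w"),
               complete = c("beta", "alpha1", "w")),
    FQL = list(partial = c("beta", "alpha1", "alpha2"),
               complete = c("beta", "alpha1", "alpha2")),
    EWA = list(partial = c("beta", "phi", "rho"),
               complete = c("beta", "phi", "rho", "delta_imit")),
    SBE = list(partial = c("beta", "alpha1"), complete = c("beta", "alpha1")),
    RelAsym = list(partial = c("beta", "alpha1", "alpha_conf", "alpha_disc"),
                   complete = c("beta", "alpha1", "alpha_conf", "alpha_disc")),
    OL1 = list(partial = c("beta", "alpha1"),
               complete = c("beta", "alpha1", "w")),
    OL2 = list(partial = c("beta", "alpha1", "alpha2"),
               complete = c("beta", "alpha1", "alpha2", "w"))
  )
  out <- lapply(names(base), function(key) {
    regs <- names(base[[key]])
    list(key = key, id = .MODEL_IDS[[key]], regimes = regs,
         par_names = base[[key]])
  })
  names(out) <- names(base)
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("partial", "complete"))
    out <- out[vapply(out, function(m) regime %in% m$regimes, logical(1))]
  }
  out
}

# resolve one model for one regime; errors on invalid combinations
.model_info <- function(model, regime) {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model key: ", model, call. = FALSE)
  m <- reg[[model]]
  if (!regime %in% m$regimes)
    stop("model ", model, " is not defined for ", regime, " feedback",
         call. = FALSE)
  pn <- m$par_names[[regime]]
  list(key = model, id = m$id, regime = regime, par_names = pn,
       k = length(pn))
}

# validate a parameter vector against the registry
.check_params <- function(params, info) {
  miss <- setdiff(info$par_names, names(params))
  if (length(miss))
    stop("missing parameter(s) for ", info$key, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- params[info$par_names]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("parameters out of bounds [0, 1] for ", info$key, call. = FALSE)
  if (info$key == "OL2" && p[["alpha2"]] > p[["alpha1"]] + 1e-12)
    stop("OL2 requires alpha2 <= alpha1", call. = FALSE)
  p
}

# one simulation/replay step shared by the simulator: choice probability of
# `first` stimulus, given the current state
.choice_prob <- function(model, state, first, second, params, regime) {
  if (model == "SBE") {
    sbe_trial_likelihood(state$hist_r[[first]], state$hist_t[[first]],
                         state$hist_r[[second]], state$hist_t[[second]],
                         state$t + 1L, params[["alpha1"]], params[["beta"]],
                         q0 = state$q0)
  } else {
    softmax_choice_prob(state$q[first], state$q[second], params[["beta"]])
  }
}

# apply one trial's update for any registered model (R reference path)
.model_step <- function(model, state, fb, params, regime) {
  switch(model,
    SQL = sql_step(state, fb, params, regime, extended = FALSE),
    SQL2 = sql_step(state, fb, params, regime, extended = TRUE),
    RPD = rp_step(state, fb, params, regime, "RPD"),
    RPA = rp_step(state, fb, params, regime, "RPA"),
    RPM = rp_step(state, fb, params, regime, "RPM"),
    Dif = dif_step(state, fb, params, regime),
    Hyb = hyb_step(state, fb, params, regime),
    FQL = fql_step(state, fb, params, regime),
    EWA = ewa_step(state, fb, params, regime),
    SBE = state,  # value state is the sample history, updated below
    RelAsym = relasym_step(state, fb, params, regime),
    OL1 = ol_step(state, fb, params, regime),
    OL2 = ol_step(state, fb, params, regime),
    stop("unknown model key: ", model))
}

# advance the bookkeeping shared by all models (trial counter, histories)
.advance_state <- function(state, fb, regime, trial_index) {
  state$t <- trial_index
  state$hist_r[[fb$chosen]] <- c(state$hist_r[[fb$chosen]], fb$r_chosen)
  state$hist_t[[fb$chosen]] <- c(state$hist_t[[fb$chosen]], trial_index)
  if (regime == "complete" && !is.na(fb$r_unchosen)) {
    state$hist_r[[fb$unchosen]] <- c(state$hist_r[[fb$unchosen]], fb$r_unchosen)
    state$hist_t[[fb$unchosen]] <- c(state$hist_t[[fb$unchosen]], trial_index)
  }
  state
}
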