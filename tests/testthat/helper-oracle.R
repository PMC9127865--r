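# Independently coded brute-force reference implementations used to
# cross-check the package's update rules and likelihoods.  Deliberately
# written in a different style (flat vectors, explicit if/else chains,
# naive softmax) and kept free of any package internals.

oracle_softmax <- function(qc, qu, beta) {
  # naive two-term softmax; fine at the value scales used in tests
  exp(beta * qc) / (exp(beta * qc) + exp(beta * qu))
}

# One update step.  st is a plain list: q (length 4), v (length 2),
# n (length 4), hr/ht (length-4 lists of reward/trial vectors).
# fb: ch, un, cx, rch, run (NA if partial).  pa: named parameter vector.
oracle_step <- function(model, st, fb, pa, regime) {
  ch <- fb$ch; un <- fb$un; cx <- fb$cx
  rch <- fb$rch; run <- fb$run
  cp <- regime == "complete"
  if (model == "SQL") {
    st$q[ch] <- st$q[ch] + pa["alpha1"] * (rch - st$q[ch])
  } else if (model == "SQL2") {
    st$q[ch] <- st$q[ch] + pa["alpha1"] * (rch - st$q[ch])
    st$q[un] <- st$q[un] + pa["alpha2"] * (run - st$q[un])
  } else if (model %in% c("RPD", "RPA", "RPM")) {
    if (model == "RPD") rx <- rch
    if (model == "RPA") rx <- if (cp) (rch + run) / 2 else (rch + st$q[un]) / 2
    if (model == "RPM") rx <- if (cp) max(rch, run) else max(rch, st$q[un])
    st$v[cx] <- st$v[cx] + pa["alpha1"] * (rx - st$v[cx])
    st$q[ch] <- st$q[ch] + pa["alpha2"] * ((rch - st$v[cx]) - st$q[ch])
    if (cp)
      st$q[un] <- st$q[un] + pa["alpha3"] * ((run - st$v[cx]) - st$q[un])
  } else if (model == "Dif") {
    st$q[ch] <- st$q[ch] + pa["alpha1"] * ((rch - run) - st$q[ch])
  } else if (model == "Hyb") {
    cf <- if (cp) run else st$q[un]
    rhyb <- pa["w"] * rch + (1 - pa["w"]) * (rch - cf)
    st$q[ch] <- st$q[ch] + pa["alpha1"] * (rhyb - st$q[ch])
  } else if (model == "FQL") {
    st$q[ch] <- st$q[ch] + pa["alpha1"] * (rch - st$q[ch])
    st$q[un] <- pa["alpha2"] * st$q[un]
  } else if (model == "EWA") {
    n0 <- st$n[ch]; n1 <- pa["rho"] * n0 + 1
    st$q[ch] <- (st$q[ch] * n0 * pa["phi"] + rch) / n1
    st$n[ch] <- n1
    if (cp) {
      m0 <- st$n[un]; m1 <- pa["rho"] * m0 + 1
      st$q[un] <- (st$q[un] * m0 * pa["phi"] + pa["delta_imit"] * run) / m1
      st$n[un] <- m1
    }
  } else if (model == "SBE") {
    # value state is the sample history; appended by oracle_advance
  } else if (model == "RelAsym") {
    rx <- if (cp) (rch + run) / 2 else (rch + st$q[un]) / 2
    st$v[cx] <- st$v[cx] + pa["alpha1"] * (rx - st$v[cx])
    d1 <- (rch - st$v[cx]) - st$q[ch]
    if (d1 > 0) st$q[ch] <- st$q[ch] + pa["alpha_conf"] * d1
    else st$q[ch] <- st$q[ch] + pa["alpha_disc"] * d1
    if (cp) {
      d2 <- (run - st$v[cx]) - st$q[un]
      if (d2 < 0) st$q[un] <- st$q[un] + pa["alpha_conf"] * d2
      else st$q[un] <- st$q[un] + pa["alpha_disc"] * d2
    }
  } else if (model %in% c("OL1", "OL2")) {
    a1 <- pa["alpha1"]
    a2 <- if (model == "OL1") a1 else pa["alpha2"]
    if (cp) {
      w <- pa["w"]
      d <- (w * rch + (1 - w) * (rch - run)) - st$q[ch]
    } else d <- rch - st$q[ch]
    st$q[ch] <- st$q[ch] + a1 * d
    st$q[un] <- st$q[un] - a2 * d
  } else stop("oracle: unknown model ", model)
  st
}

oracle_advance <- function(st, fb, regime, t) {
  st$hr[[fb$ch]] <- c(st$hr[[fb$ch]], fb$rch)
  st$ht[[fb$ch]] <- c(st$ht[[fb$ch]], t)
  if (regime == "complete") {
    st$hr[[fb$un]] <- c(st$hr[[fb$un]], fb$run)
    st$ht[[fb$un]] <- c(st$ht[[fb$un]], t)
  }
  st
}

oracle_init <- function(q0 = 0) {
  list(q = rep(q0, 4), v = rep(q0, 2), n = rep(1, 4),
       hr = rep(list(numeric(0)), 4), ht = rep(list(integer(0)), 4))
}

# recency-sampling trial probability for the SBE model, by direct double sum
oracle_sbe_prob <- function(st, ch, un, t, alpha, beta, q0 = 0) {
  wts <- function(s) {
    r <- st$hr[[s]]
    if (length(r) == 0) return(cbind(v = q0, w = 1))
    w <- alpha * (1 - alpha)^(t - st$ht[[s]])
    cbind(v = r, w = w / sum(w))
  }
  a <- wts(ch); b <- wts(un)
  tot <- 0
  for (j in seq_len(nrow(a)))
    for (k in seq_len(nrow(b)))
      tot <- tot + a[j, "w"] * b[k, "w"] *
        oracle_softmax(a[j, "v"], b[k, "v"], beta)
  tot
}

# full learning-phase NLL by naive replay
oracle_nll <- function(model, pa, trials, regime, q0 = 0) {
  st <- oracle_init(q0)
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    ch <- trials$ch[i]; un <- trials$un[i]
    if (model == "SBE") {
      p <- oracle_sbe_prob(st, ch, un, trials$t[i], pa["alpha1"],
                           pa["beta"], q0)
    } else {
      p <- oracle_softmax(st$q[ch], st$q[un], pa["beta"])
    }
    nll <- nll - log(p)
    fb <- list(ch = ch, un = un, cx = if (ch <= 2) 1 else 2,
               rch = trials$rch[i], run = trials$run[i])
    st <- oracle_step(model, st, fb, pa, regime)
    st <- oracle_advance(st, fb, regime, trials$t[i])
  }
  unname(nll)
}

# random in-bounds parameter vector for a model/regime
random_params <- function(model, regime) {
  pn <- oppolearn::model_registry()[[model]]$par_names[[regime]]
  p <- setNames(runif(length(pn)), pn)
  if (model == "OL2") p["alpha2"] <- p["alpha2"] * p["alpha1"]
  if (model == "SBE") p["alpha1"] <- runif(1, 0.05, 1)
  p
}

# random trial table on the two-context task (indices 1..4)
random_trials <- function(n, regime) {
  cx <- sample(1:2, n, replace = TRUE)
  first <- runif(n) < 0.5
  ch <- ifelse(cx == 1, ifelse(first, 1, 2), ifelse(first, 3, 4))
  un <- ifelse(cx == 1, ifelse(first, 2, 1), ifelse(first, 4, 3))
  data.frame(t = seq_len(n), ch = ch, un = un,
             rch = runif(n, 0, 100),
             run = if (regime == "complete") runif(n, 0, 100) else NA_real_)
}

# exact one-sided binomial tail by enumeration
oracle_binom_tail <- function(k, n) {
  sum(choose(n, k:n)) * 0.5^n
}

# exceedance probabilities by direct Dirichlet posterior sampling
oracle_dirichlet_xp <- function(alpha, n = 2e5) {
  draws <- sapply(alpha, function(a) rgamma(n, a))
  tabulate(apply(draws, 1, which.max), nbins = length(alpha)) / n
}

# hand-rolled trial table from a package dataset (single subject)
coded_trials <- function(data) {
  d <- data[data$phase == "learning" & !is.na(data$choice), ]
  stim <- c(A1 = 1, B = 2, A2 = 3, C = 4)
  ch <- stim[d$choice]
  lf <- stim[d$stim_left]; rt <- stim[d$stim_right]
  un <- ifelse(ch == lf, rt, lf)
  data.frame(t = d$trial, ch = ch, un = un, rch = d$r_chosen,
             run = d$r_unchosen)
}

# shared tiny fixtures
fig5_config <- function(regime = "partial")
  task_config(mu = c(A1 = 7, B = 5, A2 = 7, C = 3), sigma = 1,
              regime = regime)

# minimal learning-only dataset from a random trial table
trials_to_dataset <- function(tr, regime) {
  stim <- c("A1", "B", "A2", "C")
  d <- data.frame(subject = "s1", phase = "learning", trial = tr$t,
                  context = ifelse(tr$ch <= 2, "A1B", "A2C"),
                  stim_left = stim[tr$ch], stim_right = stim[tr$un],
                  choice = stim[tr$ch], r_chosen = tr$rch,
                  r_unchosen = tr$run, confidence = NA_real_,
                  estimate = NA_real_)
  attr(d, "regime") <- regime
  d
}
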