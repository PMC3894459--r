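# small networks and stimuli reused across tests

tiny_net <- function(n_channels = 8, fan_out = 3, nu = 1, ...) {
  build_network(network_params(n_channels = n_channels, fan_out = fan_out,
                               nu = nu, ...))
}

# the canonical two-pulse drive: 5.5 ms pulses in channels 5 then 9,
# lag 9 ms, repeated n_reps times with a 120 ms period (12 channels)
two_pulse_drive <- function(n_reps = 30, dt = 0.1) {
  period <- as.integer(round(120 / dt))
  dr <- matrix(0, 12, period)
  p <- as.integer(round(5.5 / dt)) - 1L
  t5 <- as.integer(round(5 / dt)) + 1L
  t9 <- as.integer(round(14 / dt)) + 1L
  dr[5, t5:(t5 + p)] <- 1
  dr[9, t9:(t9 + p)] <- 1
  dr[, rep(seq_len(period), n_reps)]
}

# independent Mann-Whitney oracle: U / (n1 n2) with 0.5 tie credit
mw_auc <- function(target, nontarget) {
  mean(outer(target, nontarget, ">") + 0.5 * outer(target, nontarget, "=="))
}

# independent hand-formula evaluation of specific information and SSI from
# a conditional table (classes x responses), uniform prior
hand_info <- function(cond) {
  k <- nrow(cond)
  prior <- rep(1 / k, k)
  pr <- as.numeric(prior %*% cond)
  post <- (prior * cond) / rep(pr, each = k)
  h <- 0
  for (i in seq_len(k)) h <- h - prior[i] * log2(prior[i])
  isp <- numeric(ncol(cond))
  for (j in seq_len(ncol(cond))) {
    s <- 0
    for (i in seq_len(k))
      if (post[i, j] > 0) s <- s + post[i, j] * log2(post[i, j])
    isp[j] <- h + s
  }
  ssi <- numeric(k)
  for (i in seq_len(k)) ssi[i] <- sum(cond[i, ] * isp)
  list(isp = isp, ssi = ssi)
}

# naive triple-loop evaluation of the connectivity prediction
naive_predict <- function(a, nu, epsilon, d0 = 0, dt_ms = 1,
                          clip_negative = TRUE) {
  n <- nrow(a); tn <- ncol(a)
  cm <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    dtp <- d0 + abs(x - y) * nu
    lp <- as.integer(round((dtp + epsilon) / dt_ms))
    lm <- as.integer(round((dtp - epsilon) / dt_ms))
    s <- 0
    for (t in seq_len(tn)) {
      ap <- if (t + lp >= 1 && t + lp <= tn) a[y, t + lp] else 0
      am <- if (t + lm >= 1 && t + lm <= tn) a[y, t + lm] else 0
      s <- s + a[x, t] * ap - a[x, t] * am
    }
    cm[x, y] <- s
  }
  if (clip_negative) cm[cm < 0] <- 0
  cm
}
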