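# Independent oracles used across the suite. Each re-derives its quantity by
# brute force / direct formula, deliberately not sharing code with R/.

# Exact rejection probability by full enumeration of the joint stage-1 /
# stage-2 outcome space (no convolution shortcuts).
enum_reject_prob <- function(r1, n1, r, n, p) {
  total <- 0
  for (x1 in 0:n1) {
    if (x1 <= r1) next
    for (x2 in 0:(n - n1)) {
      if (x1 + x2 >= r + 1)
        total <- total + dbinom(x1, n1, p) * dbinom(x2, n - n1, p)
    }
  }
  total
}

# Naive feasible-design scan: every (r1, n1, r, n) with n <= n_max, checking
# the error constraints by enum_reject_prob-style sums; returns min EN(p0).
naive_min_en <- function(p0, p1, alpha, beta, n_max) {
  best_en <- Inf
  for (n in 2:n_max) for (n1 in 1:(n - 1)) for (r1 in 0:(n1 - 1)) {
    x1 <- (r1 + 1):n1
    for (r in r1:(n - 1)) {
      size <- sum(dbinom(x1, n1, p0) *
                    pbinom(r - x1, n - n1, p0, lower.tail = FALSE))
      if (size > alpha) next
      pw <- sum(dbinom(x1, n1, p1) *
                  pbinom(r - x1, n - n1, p1, lower.tail = FALSE))
      if (pw < 1 - beta) break  # power only falls as r grows
      en <- n1 + (1 - pbinom(r1, n1, p0)) * (n - n1)
      best_en <- min(best_en, en)
      break  # smallest feasible r found for this (n, n1, r1)
    }
  }
  best_en
}

# Stagewise-ordering tail by exhaustive enumeration of continuing paths.
enum_stagewise_p <- function(r1, n1, n2, s_total, p) {
  total <- 0
  for (x1 in 0:n1) {
    if (x1 <= r1) next
    for (x2 in 0:n2) {
      if (x1 + x2 >= s_total)
        total <- total + dbinom(x1, n1, p) * dbinom(x2, n2, p)
    }
  }
  total
}

# Weighted KS enrichment score by an explicit element-by-element loop
# (positive extremum preferred on an exact |max| = |min| tie).
enum_gsea_es <- function(stats, hit, weight = 1) {
  n <- length(stats)
  nr <- sum(abs(stats[hit])^weight)
  run <- 0; hi <- 0; lo <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (nr > 0) abs(stats[i])^weight / nr else 1 / sum(hit)
    } else {
      run <- run - 1 / (n - sum(hit))
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi >= -lo) hi else lo
}

# Two-sided exact rank-sum p-value by full enumeration of group assignments.
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC as the concordant-pair fraction (+1/2 per tie), pair by pair.
enum_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Efron-tie Cox partial log-likelihood for a single binary covariate,
# maximised by direct 1-d optimisation.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(dead)
    eta_dead <- beta * x[dead]
    s_risk <- sum(exp(beta * x[risk]))
    s_dead <- sum(exp(eta_dead))
    ll <- ll + sum(eta_dead)
    for (j in seq_len(d) - 1)
      ll <- ll - log(s_risk - (j / d) * s_dead)
  }
  ll
}

oracle_cox_hr <- function(time, event, x) {
  opt <- optimize(function(b) -efron_loglik(b, time, event, x),
                  interval = c(-10, 10), tol = 1e-10)
  exp(opt$minimum)
}
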