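# Independent oracles and fixture builders. Everything here is deliberately
# written by a different route than the package code it checks: explicit
# loops, series expansions, bisection, brute-force pair enumeration.

random_candidates <- function(n, sigma_max = 1, zero_sigma = FALSE,
                              h_max = 1, with_outcomes = FALSE) {
  df <- data.frame(
    id = sprintf("p%03d", seq_len(n)),
    meld = sample(6:40, n, replace = TRUE),
    mu = runif(n, 0, 5),
    sigma = if (zero_sigma) rep(0, n) else runif(n, 0, sigma_max),
    h = runif(n, 0, h_max),
    blood_type = sample(c("O", "A", "B", "AB"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (with_outcomes) {
    df$survival_time <- runif(n, 0, 8)
    df$event <- rbinom(n, 1, 0.7)
  }
  df
}

# Brute-force HTU selection: explicit pairwise probability matrix, explicit
# dominance filtering, explicit lexicographic minimization.
oracle_select_htu <- function(df, alpha, hcrit) {
  n <- nrow(df)
  z <- qnorm(1 - alpha)
  p <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(df$sigma[i]^2 + df$sigma[j]^2)
    p[i, j] <- if (d == 0) {
      if (df$mu[i] > df$mu[j]) 1 else if (df$mu[i] < df$mu[j]) 0 else 0.5
    } else pnorm((df$mu[i] - df$mu[j]) / d)
  }
  dominated <- logical(n)
  for (j in seq_len(n))
    for (i in seq_len(n))
      if (i != j && p[i, j] > 1 - alpha) dominated[j] <- TRUE
  ts <- which(!dominated)
  if (length(ts) == 1L) return(df$id[ts])
  ni <- integer(length(ts))
  for (k in seq_along(ts)) {
    cnt <- 0L
    for (j in seq_len(n))
      if (j != ts[k] && df$h[j] >= hcrit) cnt <- cnt + 1L
    ni[k] <- cnt
  }
  keep <- ts[ni == min(ni)]
  madj <- df$mu[keep] - z * df$sigma[keep]
  df$id[keep[which.max(madj)]]
}

# Standard normal CDF via the Maclaurin series of erf (independent of pnorm).
phi_series <- function(x) {
  erf <- function(t) {
    k <- 0:40
    2 / sqrt(pi) * sum((-1)^k * t^(2 * k + 1) / (factorial(k) * (2 * k + 1)))
  }
  0.5 * (1 + erf(x / sqrt(2)))
}

# Standard normal quantile by bisection on the series CDF.
qnorm_bisect <- function(p, tol = 1e-10) {
  lo <- -10
  hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (phi_series(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# RMST oracle: evaluate the right-continuous step function with stats::stepfun
# and sum rectangle areas between breakpoints.
rmst_stepfun_oracle <- function(curve, tau) {
  if (length(curve$event_times) == 0L) return(tau)
  s <- stats::stepfun(curve$event_times, c(1, curve$survival_probs),
                      right = FALSE)
  breaks <- sort(unique(c(0, curve$event_times[curve$event_times < tau], tau)))
  sum(s(head(breaks, -1L)) * diff(breaks))
}

# Kendall tau-b by O(n^2) pair enumeration.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sx <- sign(x[i] - x[j])
    sy <- sign(y[i] - y[j])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    s <- sx * sy
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Spearman rho as Pearson on average ranks, computed from first principles.
rho_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exponential rate from target restricted mean, by plain bisection.
rate_bisect_oracle <- function(mu, tau, tol = 1e-12) {
  f <- function(l) (1 - exp(-l * tau)) / l - mu
  lo <- 1e-12
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Cohort priority order by sequential removal: repeatedly pick the remaining
# candidate with the fewest others above hcrit, breaking ties by largest
# adjusted benefit (the epistemic screen bypassed).
sequential_removal_order <- function(df, params) {
  madj <- df$mu - params$z * df$sigma
  remaining <- seq_len(nrow(df))
  out <- integer(0)
  while (length(remaining)) {
    ni <- vapply(remaining, function(i)
      sum(df$h[setdiff(remaining, i)] >= params$hcrit), integer(1L))
    cand <- remaining[ni == min(ni)]
    pick <- cand[which.max(madj[cand])]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

# Manifest comparison helper: everything except the wall-clock timestamp.
manifest_without_timestamp <- function(path) {
  m <- jsonlite::read_json(path)
  m$timestamp <- NULL
  m
}
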