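#' Upper-tail standard normal quantile from an error tolerance
#'
#' @param alpha Probability in (0, 1).
#' @return `qnorm(1 - alpha)`, the z used both in the epistemic screen margin
#'   and in the uncertainty-adjusted benefit.
#' @examples
#' z_from_alpha(0.5)   # 0
#' z_from_alpha(0.05)  # 1.6449
#' @export
z_from_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must be in (0, 1)")
  qnorm(1 - alpha)
}

#' Probability that one candidate's benefit exceeds another's
#'
#' Treating each candidate's post-transplant benefit as normally distributed
#' with mean `mu` and standard deviation `sigma`, returns
#' `P(U_i > U_j) = pnorm((mu_i - mu_j) / sqrt(sigma_i^2 + sigma_j^2))`.
#' When both sigmas are zero the comparison is deterministic: 1, 0 or 0.5
#' according to the sign of `mu_i - mu_j`.
#'
#' @param mu_i,mu_j Benefit means (years).
#' @param sigma_i,sigma_j Predictive standard deviations (years, `>= 0`).
#' @return Probability in \[0, 1\]; vectorized.
#' @export
superiority_probability <- function(mu_i, sigma_i, mu_j, sigma_j) {
  if (any(sigma_i < 0) || any(sigma_j < 0)) stop("sigma must be >= 0")
  denom <- sqrt(sigma_i^2 + sigma_j^2)
  d <- mu_i - mu_j
  out <- ifelse(denom > 0, pnorm(d / denom),
                ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5)))
  out
}

# Pairwise matrix P[i, j] = P(U_i > U_j); diagonal set to 0.5.
#' @noRd
superiority_matrix <- function(mu, sigma) {
  v <- sigma^2
  denom <- sqrt(outer(v, v, `+`))
  d <- outer(mu, mu, `-`)
  p <- matrix(0.5, length(mu), length(mu))
  pos <- denom > 0
  p[pos] <- pnorm(d[pos] / denom[pos])
  deg <- !pos & d > 0
  p[deg] <- 1
  deg <- !pos & d < 0
  p[deg] <- 0
  diag(p) <- 0.5
  p
}

#' Epistemic screen: the undominated tie set
#'
#' Candidate j is excluded when some other candidate i beats it with
#' confidence: `P(U_i > U_j) > 1 - alpha` (strict inequality, so a
#' probability exactly at the boundary does not exclude). The returned tie
#' set is the set of candidates no one confidently dominates; it is never
#' empty, and it is a singleton exactly when one candidate confidently beats
#' all others.
#'
#' @param pool An [new_pool()] object or candidate data frame.
#' @param params [htu_params()].
#' @return Character vector of surviving candidate ids, in pool order.
#' @export
epistemic_screen <- function(pool, params = htu_params()) {
  pool <- as_pool(pool)
  df <- pool$candidates
  p <- superiority_matrix(df$mu, df$sigma)
  dominated <- apply(p > 1 - params$alpha, 2L, any)
  df$id[!dominated]
}

#' Catastrophic-harm count
#'
#' `N_i` is the number of *other* pool members whose 90-day waitlist
#' mortality meets or exceeds `hcrit` — the patients who would remain in
#' catastrophic danger if candidate `i` received the organ. The harm stage of
#' the HTU rule minimizes this count.
#'
#' @param pool Pool or candidate data frame.
#' @param id Candidate id (must be in the pool).
#' @param hcrit Harm threshold in \[0, 1\]; the comparison is inclusive
#'   (`h >= hcrit`).
#' @return Nonnegative integer count.
#' @export
harm_count <- function(pool, id, hcrit) {
  pool <- as_pool(pool)
  df <- pool$candidates
  i <- match(id, df$id)
  if (is.na(i)) stop("candidate ", id, " not in pool")
  sum(df$h[-i] >= hcrit)
}

# All N_i at once: C - 1{H_i >= hcrit} with C the catastrophic-set size.
#' @noRd
harm_counts_all <- function(h, hcrit) {
  above <- h >= hcrit
  sum(above) - as.integer(above)
}

#' Uncertainty-adjusted benefit
#'
#' The lower prediction bound `mu - z * sigma` with `z = qnorm(1 - alpha)`:
#' the benefit a candidate can be credited with at confidence `1 - alpha`.
#' Used as the final HTU tie-breaker and as the cohort-ranking key. Not
#' clamped; it can be negative for very uncertain predictions.
#'
#' @param mu Benefit mean(s), years.
#' @param sigma Predictive standard deviation(s), years.
#' @param params [htu_params()].
#' @return Adjusted benefit in years; vectorized.
#' @export
adjusted_benefit <- function(mu, sigma, params = htu_params()) {
  mu - params$z * sigma
}

#' Allocate one organ by the harm-threshold utilitarian rule
#'
#' The sequential HTU rule:
#' \enumerate{
#'   \item \strong{Epistemic screen} — drop every candidate confidently
#'     dominated by another ([epistemic_screen()]). If one candidate
#'     dominates all others the decision ends here.
#'   \item \strong{Harm minimization} — among the screen survivors, keep the
#'     candidates minimizing `N_i`, the number of other pool members left
#'     above the catastrophic threshold (counted over the full pool).
#'   \item \strong{Benefit tie-break} — among those, pick the largest
#'     uncertainty-adjusted benefit `mu - z * sigma`; residual exact ties go
#'     to the earliest pool position.
#' }
#'
#' @param pool Pool or candidate data frame.
#' @param params [htu_params()].
#' @return An `htu_decision` audit record: `selected_id`, `stage` (one of
#'   `"screen_resolved"`, `"harm_resolved"`, `"benefit_tiebreak"`), `tie_set`,
#'   `harm_counts` (named, over the tie set), `mu_adj` (named, all
#'   candidates), and the `params` used.
#' @examples
#' pool <- data.frame(id = c("a", "b"), meld = c(30, 20),
#'                    mu = c(1.5, 4), sigma = c(0.3, 0.3),
#'                    h = c(0.5, 0.1), blood_type = "O")
#' select_htu(pool, htu_params(alpha = 0.05, hcrit = 0.30))
#' @export
select_htu <- function(pool, params = htu_params()) {
  pool <- as_pool(pool)
  df <- pool$candidates
  mu_adj <- setNames(adjusted_benefit(df$mu, df$sigma, params), df$id)
  tie_set <- epistemic_screen(pool, params)
  n_all <- setNames(harm_counts_all(df$h, params$hcrit), df$id)
  harm_counts <- n_all[tie_set]

  if (length(tie_set) == 1L) {
    selected <- tie_set
    stage <- "screen_resolved"
  } else {
    keep <- tie_set[harm_counts == min(harm_counts)]
    if (length(keep) == 1L) {
      selected <- keep
      stage <- "harm_resolved"
    } else {
      selected <- keep[which.max(mu_adj[keep])]
      stage <- "benefit_tiebreak"
    }
  }
  structure(list(selected_id = selected, stage = stage, tie_set = tie_set,
                 harm_counts = harm_counts, mu_adj = mu_adj, params = params),
            class = "htu_decision")
}

#' @export
print.htu_decision <- function(x, ...) {
  cat("HTU allocation decision\n")
  cat(sprintf("  selected : %s\n", x$selected_id))
  cat(sprintf("  stage    : %s\n", x$stage))
  cat(sprintf("  alpha    : %g (z = %.4f), hcrit = %g\n",
              x$params$alpha, x$params$z, x$params$hcrit))
  cat(sprintf("  tie set  : %s\n", paste(x$tie_set, collapse = ", ")))
  cat("  per-candidate (tie set):\n")
  for (id in x$tie_set)
    cat(sprintf("    %-10s N = %d, mu_adj = %.4f\n",
                id, x$harm_counts[[id]], x$mu_adj[[id]]))
  invisible(x)
}
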