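#' @noRd
policy_selection <- function(policy_name, selected_id, score_used) {
  structure(list(policy_name = policy_name, selected_id = selected_id,
                 score_used = score_used), class = "policy_selection")
}

#' @export
print.policy_selection <- function(x, ...) {
  cat(sprintf("%s policy selects %s (score %.4g)\n",
              x$policy_name, x$selected_id, x$score_used))
  invisible(x)
}

#' MELD-maximizing (sickest-first) selection
#'
#' The urgency baseline: pick the highest MELD score. MELD ties are broken by
#' higher short-term mortality `h` (keeping the baseline maximally
#' urgency-faithful), then by pool order.
#'
#' @param pool Pool or candidate data frame.
#' @return A `policy_selection` with `policy_name = "meld"`.
#' @export
select_meld <- function(pool) {
  pool <- as_pool(pool)
  df <- pool$candidates
  o <- order(-df$meld, -df$h)
  i <- o[1L]
  policy_selection("meld", df$id[i], df$meld[i])
}

#' Unconstrained utilitarian selection
#'
#' Pick the candidate with the largest expected benefit `mu`; ties go to the
#' earliest pool position.
#'
#' @param pool Pool or candidate data frame.
#' @return A `policy_selection` with `policy_name = "utilitarian"`.
#' @export
select_utilitarian <- function(pool) {
  pool <- as_pool(pool)
  df <- pool$candidates
  i <- which.max(df$mu)
  policy_selection("utilitarian", df$id[i], df$mu[i])
}

#' Uncertainty-penalized utilitarian selection
#'
#' Pick the candidate with the largest adjusted benefit `mu - z * sigma`.
#' Coincides with [select_utilitarian()] when all sigmas are zero or when
#' `alpha = 0.5` (z = 0). Serves as the reference policy for the degenerate
#' reductions of the HTU rule.
#'
#' @param pool Pool or candidate data frame.
#' @param params [htu_params()].
#' @return A `policy_selection` with `policy_name = "utilitarian_adj"`.
#' @export
select_utilitarian_adjusted <- function(pool, params = htu_params()) {
  pool <- as_pool(pool)
  df <- pool$candidates
  madj <- adjusted_benefit(df$mu, df$sigma, params)
  i <- which.max(madj)
  policy_selection("utilitarian_adj", df$id[i], madj[i])
}

# Dispatch a policy by its configuration name.
#' @noRd
select_policy <- function(pool, policy, params = htu_params()) {
  switch(policy,
    meld = select_meld(pool),
    utilitarian = select_utilitarian(pool),
    utilitarian_adj = select_utilitarian_adjusted(pool, params),
    htu = {
      d <- select_htu(pool, params)
      policy_selection("htu", d$selected_id, d$mu_adj[[d$selected_id]])
    },
    stop("unknown policy: ", policy))
}
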