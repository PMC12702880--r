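#' Kaplan-Meier fit of post-transplant survival
#'
#' Product-limit estimate of the survival function from (possibly censored)
#' survival times, via [survival::survfit()]. At tied times deaths are
#' processed before censorings (the standard convention).
#'
#' @param times Nonnegative survival/censoring times, years.
#' @param events Event indicators: 1 = death observed, 0 = censored.
#' @return A `km_curve`: `event_times` (times with at least one death),
#'   `survival_probs` (the step value of S-hat just after each), `n_at_risk`,
#'   and `n` (sample size).
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))
#' @export
km_fit <- function(times, events) {
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival_probs = fit$surv[keep],
                 n_at_risk = fit$n.risk[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              x$n, length(x$event_times)))
  if (length(x$event_times))
    print(data.frame(time = x$event_times, n_risk = x$n_at_risk,
                     surv = x$survival_probs))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlim = NULL, ylab = "Survival", xlab = "Years",
                          ...) {
  t <- c(0, x$event_times)
  s <- c(1, x$survival_probs)
  if (is.null(xlim)) xlim <- c(0, max(t, 1))
  plot(t, s, type = "s", ylim = c(0, 1), xlim = xlim,
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Restricted mean survival time
#'
#' Exact step-function integral of the Kaplan-Meier curve from 0 to the
#' horizon `tau`: the mean years lived in the first `tau` years.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param tau Horizon in years (> 0); 5 throughout this package.
#' @return RMST in years, always `<= tau`.
#' @export
rmst <- function(curve, tau = 5) {
  if (!inherits(curve, "km_curve")) stop("curve must be a km_curve")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be > 0")
  before <- curve$event_times < tau
  breaks <- c(0, curve$event_times[before], tau)
  heights <- c(1, curve$survival_probs[before])
  sum(diff(breaks) * heights)
}

#' Compare recipient outcomes across allocation policies
#'
#' Summarizes a per-pool selection table: one pooled Kaplan-Meier curve and
#' 5-year RMST per policy (over all that policy's recipients), plus the
#' per-pool paired difference in outcome between two policies
#' (default HTU minus MELD) with its mean and standard error across pools
#' (`SE = sd / sqrt(n_pools)`).
#'
#' The per-pool outcome is `min(survival_time, tau)` — each recipient's
#' realized restricted survival — when `gain_scale = "simulated_survival"`,
#' or the predicted benefit `mu` when `gain_scale = "predicted_mu"`.
#'
#' @param per_pool Data frame with columns `pool`, `policy`, `id`, `mu`, `h`,
#'   `meld`, `survival_time`, `event` (one row per pool x policy), as
#'   produced by [run_comparison()].
#' @param tau RMST horizon, years.
#' @param gain_scale `"simulated_survival"` or `"predicted_mu"`.
#' @param diff_policies Length-2 character: difference is first minus second.
#' @return A `policy_comparison`: per-policy `curves` and `rmst`, and `diff`
#'   (`values`, `mean`, `se`, `policies`).
#' @export
compare_policies_outcomes <- function(per_pool, tau = 5,
                                      gain_scale = c("simulated_survival",
                                                     "predicted_mu"),
                                      diff_policies = c("htu", "meld")) {
  gain_scale <- match.arg(gain_scale)
  policies <- unique(per_pool$policy)
  curves <- list()
  rmsts <- setNames(numeric(0), character(0))
  for (p in policies) {
    rows <- per_pool[per_pool$policy == p, ]
    has_outcome <- !is.na(rows$survival_time)
    if (sum(has_outcome) < 2)
      stop("policy ", p, " has fewer than 2 recipients with outcomes")
    curves[[p]] <- km_fit(rows$survival_time[has_outcome],
                          rows$event[has_outcome])
    rmsts[p] <- rmst(curves[[p]], tau)
  }
  outcome_of <- function(rows) {
    if (gain_scale == "simulated_survival") pmin(rows$survival_time, tau)
    else rows$mu
  }
  a <- per_pool[per_pool$policy == diff_policies[1L], ]
  b <- per_pool[per_pool$policy == diff_policies[2L], ]
  a <- a[order(a$pool), ]
  b <- b[order(b$pool), ]
  if (!identical(a$pool, b$pool))
    stop("policies ", paste(diff_policies, collapse = "/"),
         " do not cover the same pools")
  d <- outcome_of(a) - outcome_of(b)
  structure(list(curves = curves, rmst = rmsts, tau = tau,
                 gain_scale = gain_scale,
                 diff = list(policies = diff_policies, values = d,
                             mean = mean(d),
                             se = sd(d) / sqrt(length(d)))),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison (RMST horizon %g y, gain scale: %s)\n",
              x$tau, x$gain_scale))
  for (p in names(x$rmst))
    cat(sprintf("  %-16s RMST = %.4f y (n = %d recipients)\n",
                p, x$rmst[[p]], x$curves[[p]]$n))
  cat(sprintf("  gain (%s - %s): mean %.4f y, SE %.4f across %d pools\n",
              x$diff$policies[1L], x$diff$policies[2L],
              x$diff$mean, x$diff$se, length(x$diff$values)))
  invisible(x)
}
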