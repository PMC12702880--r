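#' Offer-pool simulation configuration
#'
#' Settings of the Monte-Carlo policy-comparison harness: 2,000 pools of 10
#' ABO-compatible candidates by default, HTU at baseline `alpha = 0.05`,
#' `hcrit = 0.30`, and a sensitivity grid sweeping `hcrit` from 0.10 to 0.70
#' with `alpha` varied around its baseline.
#'
#' @param n_pools Number of simulated offer pools.
#' @param pool_size Candidates per pool (>= 2).
#' @param alpha,hcrit Baseline HTU parameters.
#' @param hcrit_grid,alpha_grid Sensitivity grids (the sweep runs their
#'   product).
#' @param urgent_ref Fixed reference threshold defining an "urgent"
#'   selection for frontier reporting. Held at 0.30 across all grid points so
#'   the urgency axis stays comparable while `hcrit` is swept.
#' @param enforce_abo Draw a donor blood type per pool and sample only
#'   compatible candidates.
#' @param donor_blood_type_freqs Donor ABO sampling weights.
#' @param gain_scale `"simulated_survival"` (realized `min(T, 5)`, default)
#'   or `"predicted_mu"` (predicted-benefit scale, cheaper; used where only
#'   the ordering of settings matters).
#' @param seed Integer RNG seed for pool construction.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pools = 2000, pool_size = 10,
                              alpha = 0.05, hcrit = 0.30,
                              hcrit_grid = seq(0.10, 0.70, by = 0.10),
                              alpha_grid = c(0.01, 0.05, 0.10),
                              urgent_ref = 0.30, enforce_abo = TRUE,
                              donor_blood_type_freqs = c(O = 0.45, A = 0.40,
                                                         B = 0.11, AB = 0.04),
                              gain_scale = c("simulated_survival",
                                             "predicted_mu"),
                              seed = 1L) {
  gain_scale <- match.arg(gain_scale)
  if (n_pools < 1) stop("n_pools must be >= 1")
  if (pool_size < 2) stop("pool_size must be >= 2")
  if (any(c(hcrit, hcrit_grid, urgent_ref) < 0) ||
      any(c(hcrit, hcrit_grid, urgent_ref) > 1))
    stop("harm thresholds must be in [0, 1]")
  if (!length(hcrit_grid) || !length(alpha_grid)) stop("grids must be non-empty")
  structure(list(n_pools = as.integer(n_pools),
                 pool_size = as.integer(pool_size),
                 alpha = alpha, hcrit = hcrit, hcrit_grid = hcrit_grid,
                 alpha_grid = alpha_grid, urgent_ref = urgent_ref,
                 enforce_abo = enforce_abo,
                 donor_blood_type_freqs = donor_blood_type_freqs,
                 gain_scale = gain_scale, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Build simulated offer pools from a cohort
#'
#' Samples `n_pools` pools of `pool_size` candidates from the cohort with
#' replacement across pools (a candidate may appear in many pools) but
#' without duplication within a pool (a patient cannot appear twice in one
#' match run). With `enforce_abo`, a donor blood type is drawn per pool and
#' only compatible candidates are eligible for it. Reproducible from the
#' config seed.
#'
#' @param cohort Candidate data frame.
#' @param config [simulation_config()].
#' @return List of [new_pool()] objects.
#' @export
build_pools <- function(cohort, config = simulation_config()) {
  cohort <- validate_candidates(cohort)
  set.seed(config$seed)
  n <- nrow(cohort)
  if (config$enforce_abo) {
    eligible <- lapply(setNames(.BLOOD_TYPES, .BLOOD_TYPES), function(bt)
      which(abo_compatible(bt, cohort$blood_type)))
    donors <- sample(names(config$donor_blood_type_freqs), config$n_pools,
                     replace = TRUE, prob = config$donor_blood_type_freqs)
  } else {
    donors <- rep(NA_character_, config$n_pools)
  }
  pools <- vector("list", config$n_pools)
  for (k in seq_len(config$n_pools)) {
    if (config$enforce_abo) {
      idx_pool <- eligible[[donors[k]]]
      if (length(idx_pool) < config$pool_size)
        stop("only ", length(idx_pool), " candidates compatible with donor ",
             donors[k], "; need ", config$pool_size)
      take <- idx_pool[sample.int(length(idx_pool), config$pool_size)]
      pools[[k]] <- new_pool(cohort[take, ], donors[k])
    } else {
      take <- sample.int(n, config$pool_size)
      pools[[k]] <- new_pool(cohort[take, ])
    }
  }
  pools
}

# One row per pool x policy with the selected recipient's covariates.
#' @noRd
selection_table <- function(pools, params, policies) {
  rows <- vector("list", length(pools) * length(policies))
  r <- 0L
  for (k in seq_along(pools)) {
    df <- pools[[k]]$candidates
    for (p in policies) {
      sel <- select_policy(pools[[k]], p, params)
      i <- match(sel$selected_id, df$id)
      r <- r + 1L
      rows[[r]] <- data.frame(pool = k, policy = p, id = df$id[i],
                              mu = df$mu[i], h = df$h[i], meld = df$meld[i],
                              survival_time = df$survival_time[i],
                              event = df$event[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the policy comparison over simulated pools
#'
#' Applies each policy to every pool, records the selected recipient and
#' outcome, and summarizes with [compare_policies_outcomes()]: pooled
#' Kaplan-Meier curves, 5-year RMST per policy, and the per-pool HTU-minus-
#' MELD outcome difference (mean and SE across pools).
#'
#' @param pools List of pools from [build_pools()].
#' @param params [htu_params()].
#' @param policies Policy names among `"meld"`, `"htu"`, `"utilitarian"`,
#'   `"utilitarian_adj"`; the first two are required for the summary
#'   difference.
#' @param gain_scale See [compare_policies_outcomes()].
#' @param tau RMST horizon, years.
#' @return List with `per_pool` (selection table) and `comparison`
#'   (`policy_comparison`).
#' @export
run_comparison <- function(pools, params = htu_params(),
                           policies = c("meld", "htu"),
                           gain_scale = c("simulated_survival",
                                          "predicted_mu"),
                           tau = 5) {
  gain_scale <- match.arg(gain_scale)
  if (!length(pools)) stop("need at least one pool")
  per_pool <- selection_table(pools, params, policies)
  comparison <- compare_policies_outcomes(per_pool, tau = tau,
                                          gain_scale = gain_scale,
                                          diff_policies = c("htu", "meld"))
  list(per_pool = per_pool, comparison = comparison)
}

#' Harm-threshold / confidence sensitivity sweep
#'
#' Re-runs the HTU selection on the *same* pools (common random numbers) at
#' every `(hcrit, alpha)` grid point, recording the mean gain of HTU over the
#' MELD selection and the fraction of pools in which HTU selected an urgent
#' candidate (`h >= urgent_ref`, a fixed reference). Sweeping `hcrit` traces
#' the urgency-efficiency frontier: tighter thresholds protect urgent
#' candidates at the cost of mean benefit, looser ones do the opposite.
#'
#' @param pools List of pools from [build_pools()].
#' @param config [simulation_config()] supplying the grids, `urgent_ref` and
#'   `gain_scale`.
#' @param tau Horizon used for the realized-survival outcome, years.
#' @return Data frame of frontier points: `hcrit`, `alpha`, `mean_gain`,
#'   `urgent_fraction`, `n_pools`.
#' @export
sensitivity_sweep <- function(pools, config = simulation_config(), tau = 5) {
  if (!length(pools)) stop("need at least one pool")
  outcome_of <- function(df, i) {
    if (config$gain_scale == "simulated_survival")
      pmin(df$survival_time[i], tau)
    else df$mu[i]
  }
  # MELD selection does not depend on the grid point
  meld_outcome <- vapply(pools, function(pl) {
    i <- match(select_meld(pl)$selected_id, pl$candidates$id)
    outcome_of(pl$candidates, i)
  }, numeric(1L))
  grid <- expand.grid(hcrit = config$hcrit_grid, alpha = config$alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- htu_params(alpha = grid$alpha[g], hcrit = grid$hcrit[g])
    sel_h <- numeric(length(pools))
    sel_out <- numeric(length(pools))
    for (k in seq_along(pools)) {
      df <- pools[[k]]$candidates
      i <- match(select_htu(pools[[k]], params)$selected_id, df$id)
      sel_h[k] <- df$h[i]
      sel_out[k] <- outcome_of(df, i)
    }
    res[[g]] <- data.frame(hcrit = grid$hcrit[g], alpha = grid$alpha[g],
                           mean_gain = mean(sel_out - meld_outcome),
                           urgent_fraction = mean(sel_h >= config$urgent_ref),
                           n_pools = length(pools))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
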