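#' @noRd
.BLOOD_TYPES <- c("O", "A", "B", "AB")

#' @noRd
.CANDIDATE_COLS <- c("id", "meld", "mu", "sigma", "h", "blood_type",
                     "survival_time", "event")

#' ABO donor-recipient compatibility
#'
#' Standard ABO compatibility without Rh: O donates to everyone, A to A/AB,
#' B to B/AB, AB only to AB.
#'
#' @param donor Donor blood type, one of `"O"`, `"A"`, `"B"`, `"AB"`.
#' @param recipient Recipient blood type(s), same set. Vectorized over
#'   `recipient`.
#' @return Logical, `TRUE` where the donor can give to the recipient.
#' @examples
#' abo_compatible("O", "AB")   # TRUE: universal donor
#' abo_compatible("AB", "O")   # FALSE
#' @export
abo_compatible <- function(donor, recipient) {
  if (length(donor) != 1L || !donor %in% .BLOOD_TYPES)
    stop("unknown donor blood type: ", paste(donor, collapse = ","))
  if (!all(recipient %in% .BLOOD_TYPES))
    stop("unknown recipient blood type: ",
         paste(setdiff(recipient, .BLOOD_TYPES), collapse = ","))
  switch(donor,
    O  = rep(TRUE, length(recipient)),
    A  = recipient %in% c("A", "AB"),
    B  = recipient %in% c("B", "AB"),
    AB = recipient == "AB")
}

#' Validate a candidate table
#'
#' Checks the invariants every transplant candidate must satisfy: integer MELD
#' in 6-40, predicted 5-year benefit `mu` in \[0, 5\] years, predictive
#' standard deviation `sigma >= 0`, 90-day waitlist mortality `h` in \[0, 1\],
#' a known ABO blood type, nonnegative `survival_time` when present, and
#' `event` present exactly when `survival_time` is. The first violation is
#' reported with its row number.
#'
#' @param candidates A data frame with columns `id`, `meld`, `mu`, `sigma`,
#'   `h`, `blood_type` and optionally `survival_time`, `event`.
#' @return The validated data frame, with `id` coerced to character, `meld`
#'   and `event` to integer, and missing optional columns added as `NA`.
#' @export
validate_candidates <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L)
    stop("candidates must be a non-empty data frame")
  required <- c("id", "meld", "mu", "sigma", "h", "blood_type")
  missing_cols <- setdiff(required, names(candidates))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(candidates, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  if (!"survival_time" %in% names(df)) df$survival_time <- NA_real_
  if (!"event" %in% names(df)) df$event <- NA_integer_
  df <- df[, .CANDIDATE_COLS]

  fail <- function(rows, msg) {
    if (length(rows)) stop(sprintf("row %d: %s", min(rows), msg), call. = FALSE)
  }
  n <- nrow(df)
  checks <- list(
    list(is.na(df$id) | !nzchar(df$id), "missing id"),
    list(is.na(df$meld) | df$meld != round(df$meld) |
           df$meld < 6 | df$meld > 40, "meld out of [6,40]"),
    list(is.na(df$mu) | df$mu < 0 | df$mu > 5, "mu out of [0,5]"),
    list(is.na(df$sigma) | df$sigma < 0, "sigma must be >= 0"),
    list(is.na(df$h) | df$h < 0 | df$h > 1, "h out of [0,1]"),
    list(is.na(df$blood_type) | !df$blood_type %in% .BLOOD_TYPES,
         "unknown blood_type"),
    list(!is.na(df$survival_time) & df$survival_time < 0,
         "survival_time must be >= 0"),
    list(xor(is.na(df$survival_time), is.na(df$event)),
         "event present iff survival_time present"),
    list(!is.na(df$event) & !df$event %in% c(0, 1), "event must be 0 or 1")
  )
  # report the first offending row; among its violations, the first field
  bad_rows <- lapply(checks, function(ch) which(ch[[1]]))
  first <- suppressWarnings(min(unlist(bad_rows)))
  if (is.finite(first)) {
    for (k in seq_along(checks))
      if (first %in% bad_rows[[k]]) fail(first, checks[[k]][[2]])
  }
  df$meld <- as.integer(df$meld)
  df$event <- as.integer(df$event)
  rownames(df) <- NULL
  df
}

#' Construct an offer pool
#'
#' A pool is the set of eligible candidates competing for a single donor
#' organ. Candidate ids must be unique within the pool, and when a donor
#' blood type is given every member must be ABO-compatible with it.
#'
#' @param candidates Candidate data frame (see [validate_candidates()]).
#' @param donor_blood_type Optional donor ABO type.
#' @return An object of class `htu_pool`.
#' @export
new_pool <- function(candidates, donor_blood_type = NULL) {
  df <- validate_candidates(candidates)
  if (anyDuplicated(df$id))
    stop("duplicate candidate id in pool: ", df$id[duplicated(df$id)][1L])
  if (!is.null(donor_blood_type)) {
    ok <- abo_compatible(donor_blood_type, df$blood_type)
    if (!all(ok))
      stop("candidate ", df$id[!ok][1L], " is not ABO-compatible with donor ",
           donor_blood_type)
  }
  structure(list(candidates = df, donor_blood_type = donor_blood_type),
            class = "htu_pool")
}

#' @noRd
as_pool <- function(x) {
  if (inherits(x, "htu_pool")) return(x)
  new_pool(x)
}

#' @export
print.htu_pool <- function(x, ...) {
  cat(sprintf("Offer pool: %d candidates%s\n", nrow(x$candidates),
              if (is.null(x$donor_blood_type)) ""
              else paste0(", donor blood type ", x$donor_blood_type)))
  print(x$candidates)
  invisible(x)
}

#' HTU policy parameters
#'
#' The two levers of the harm-threshold rule: the error tolerance `alpha` of
#' the epistemic screen (the rule acts on a predicted advantage only when its
#' probability exceeds `1 - alpha`) and the catastrophic harm threshold
#' `hcrit` on 90-day waitlist mortality. The derived normal quantile
#' `z = qnorm(1 - alpha)` is stored alongside and also penalizes uncertain
#' benefit in the tie-break `mu - z * sigma`.
#'
#' @param alpha Error tolerance in (0, 0.5]. Default 0.05.
#' @param hcrit Catastrophic harm threshold in \[0, 1\]. Default 0.30.
#' @return An object of class `htu_params` with elements `alpha`, `hcrit`,
#'   `z`.
#' @examples
#' htu_params()            # baseline: alpha 0.05, hcrit 0.30
#' htu_params(alpha = 0.5) # z = 0: no uncertainty penalty
#' @export
htu_params <- function(alpha = 0.05, hcrit = 0.30) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    stop("alpha must be in (0, 0.5]")
  if (!is.numeric(hcrit) || length(hcrit) != 1L || hcrit < 0 || hcrit > 1)
    stop("hcrit must be in [0, 1]")
  structure(list(alpha = alpha, hcrit = hcrit, z = qnorm(1 - alpha)),
            class = "htu_params")
}

#' @export
print.htu_params <- function(x, ...) {
  cat(sprintf("HTU policy parameters: alpha = %g (z = %.4f), hcrit = %g\n",
              x$alpha, x$z, x$hcrit))
  invisible(x)
}
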