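# Average ranks induced by sorting ascending on (a, b) lexicographically;
# rows with exactly equal (a, b) share their mean position.
#' @noRd
lexicographic_rank <- function(a, b) {
  n <- length(a)
  o <- order(a, b)
  aa <- a[o]
  bb <- b[o]
  new_grp <- c(TRUE, aa[-1L] != aa[-n] | bb[-1L] != bb[-n])
  grp <- cumsum(new_grp)
  pos <- ave(seq_len(n), grp, FUN = mean)
  r <- numeric(n)
  r[o] <- pos
  r
}

#' Cohort-level HTU priority ranks
#'
#' The scalable cohort surrogate of the HTU rule: sort lexicographically by
#' the harm proxy `N_i` (fewest others remaining above `hcrit`; ascending)
#' and then by adjusted benefit `mu - z * sigma` (descending). By the
#' identity `N_i = C - 1{H_i >= hcrit}`, this puts every candidate above the
#' harm threshold ahead of every candidate below it, ordering each group by
#' adjusted benefit. Rank 1 is the highest priority; exact key ties receive
#' average ranks. The epistemic screen plays no role at cohort level.
#'
#' @param cohort Candidate data frame.
#' @param params [htu_params()].
#' @return Numeric ranks aligned with `cohort` rows.
#' @export
htu_cohort_rank <- function(cohort, params = htu_params()) {
  df <- validate_candidates(cohort)
  ni <- harm_counts_all(df$h, params$hcrit)
  madj <- adjusted_benefit(df$mu, df$sigma, params)
  lexicographic_rank(ni, -madj)
}

#' MELD priority ranks
#'
#' Rank by MELD descending (rank 1 = highest MELD); ties share average ranks,
#' so integer MELD collapses many candidates onto identical ranks.
#'
#' @param cohort Candidate data frame.
#' @return Numeric ranks aligned with `cohort` rows.
#' @export
meld_rank <- function(cohort) {
  df <- validate_candidates(cohort)
  rank(-df$meld, ties.method = "average")
}

#' MELD vs HTU rank table
#'
#' @param cohort Candidate data frame.
#' @param params [htu_params()].
#' @return Data frame with `id`, `meld_rank`, `htu_rank` and
#'   `rank_shift = htu_rank - meld_rank` (negative = higher priority under
#'   HTU).
#' @export
rank_table <- function(cohort, params = htu_params()) {
  df <- validate_candidates(cohort)
  mr <- meld_rank(df)
  hr <- htu_cohort_rank(df, params)
  data.frame(id = df$id, meld_rank = mr, htu_rank = hr,
             rank_shift = hr - mr)
}

# Count pairs tied within a vector: sum t(t-1)/2 over tie groups.
#' @noRd
tie_pairs <- function(v) {
  t <- tabulate(match(v, unique(v)))
  sum(t * (t - 1) / 2)
}

# Strict inversions in an integer vector (pairs i < j with v[i] > v[j]),
# by merge counting: O(n log n) up to the internal sorts.
#' @noRd
count_inversions <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  m <- n %/% 2L
  left <- count_inversions_sorted(v[seq_len(m)])
  right <- count_inversions_sorted(v[(m + 1L):n])
  left$count + right$count + sum(findInterval(left$sorted - 0.5, right$sorted))
}

#' @noRd
count_inversions_sorted <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(sorted = v, count = 0))
  m <- n %/% 2L
  left <- count_inversions_sorted(v[seq_len(m)])
  right <- count_inversions_sorted(v[(m + 1L):n])
  cross <- sum(findInterval(left$sorted - 0.5, right$sorted))
  list(sorted = sort(c(left$sorted, right$sorted)),
       count = left$count + right$count + cross)
}

#' Kendall's tau-b rank concordance
#'
#' Tau with the standard tie correction:
#' `(P - Q) / sqrt((n0 - n1) (n0 - n2))` where P/Q are the concordant and
#' discordant pair counts, `n0 = n(n-1)/2` and `n1`, `n2` are the tied-pair
#' counts in each argument. Discordant pairs are counted by merge-sort
#' inversion counting, so cohort-scale vectors (tens of thousands of
#' candidates, heavily tied MELD ranks) are handled in about n log n time,
#' where a naive pair scan would be quadratic.
#'
#' @param x,y Numeric vectors of equal length (ranks or scores).
#' @return Tau-b in \[-1, 1\].
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must have equal length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  n0 <- n * (n - 1) / 2
  n1 <- tie_pairs(x)
  n2 <- tie_pairs(y)
  if (n1 == n0 || n2 == n0)
    stop("tau-b undefined: all values tied in one vector")
  nxy <- tie_pairs(paste(x, y, sep = "\r"))
  o <- order(x, y)
  ycode <- match(y[o], sort(unique(y)))
  q <- count_inversions(ycode)
  p <- n0 - n1 - n2 + nxy - q
  (p - q) / sqrt((n0 - n1) * (n0 - n2))
}

#' Spearman's rho rank concordance
#'
#' Pearson correlation of average ranks, via
#' `stats::cor(..., method = "spearman")`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must have equal length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (tie_pairs(x) == n * (n - 1) / 2 || tie_pairs(y) == n * (n - 1) / 2)
    stop("rho undefined: all values tied in one vector")
  cor(x, y, method = "spearman")
}

#' Distribution of rank shifts between MELD and HTU
#'
#' Summarizes `rank_shift = htu_rank - meld_rank` from a [rank_table()]:
#' negative shifts mean the candidate has higher priority under HTU than
#' under MELD. Because both rank columns sum to `n(n+1)/2`, the mean shift is
#' zero by construction; the interest is in the spread and the share moved up.
#'
#' @param table A [rank_table()] data frame.
#' @return List with `shifts`, `mean`, `median`, `share_negative`.
#' @export
rank_shift_distribution <- function(table) {
  stopifnot(is.data.frame(table), "rank_shift" %in% names(table))
  s <- table$rank_shift
  list(shifts = s, mean = mean(s), median = median(s),
       share_negative = mean(s < 0))
}
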