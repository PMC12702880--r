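# Exact decimal text for doubles: %.17g round-trips through read.csv.
#' @noRd
format_numeric_exact <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}

#' Read a candidate table
#'
#' Reads the comma-separated candidate schema (`id`, `meld`, `mu`, `sigma`,
#' `h`, `blood_type`, `survival_time`, `event`; the last two optional, empty
#' cells for missing values) and validates every row, reporting the row
#' number of the first violation.
#'
#' @param path File path.
#' @return Validated candidate data frame.
#' @export
read_candidate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  required <- c("id", "meld", "mu", "sigma", "h", "blood_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("candidate table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_candidates(df)
}

#' Write a candidate table
#'
#' Writes candidates in the schema [read_candidate_table()] reads. Doubles
#' are written with 17 significant digits so a round trip reproduces every
#' field exactly.
#'
#' @param candidates Candidate data frame.
#' @param path Destination path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path, force = FALSE) {
  df <- validate_candidates(candidates)
  write_table_exact(df, path, force = force)
}

# CSV writer shared by all result tables: exact doubles, refuses to
# overwrite unless forced.
#' @noRd
write_table_exact <- function(df, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- format_numeric_exact(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write result tables plus a run manifest
#'
#' Writes each table as `<name>.csv` under `dir` and a `manifest.json`
#' recording the subcommand, resolved configuration, seed, input/output
#' paths, package version and timestamp — enough to re-execute the run.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param subcommand Label of the run.
#' @param config Resolved configuration list (serialized into the manifest).
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input paths (may be empty).
#' @param force Overwrite existing files.
#' @return The manifest list, invisibly.
#' @export
write_results <- function(tables, dir, subcommand = "run", config = list(),
                          seed = NA_integer_, inputs = character(),
                          force = FALSE) {
  stopifnot(is.list(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  outputs <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    write_table_exact(tables[[nm]], path, force = force)
    outputs <- c(outputs, path)
  }
  manifest <- list(subcommand = subcommand,
                   config = config,
                   seed = seed,
                   inputs = inputs,
                   outputs = outputs,
                   package_version = as.character(packageVersion("htuAlloc")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath) && !force)
    stop("refusing to overwrite ", mpath, " (use force = TRUE)")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
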