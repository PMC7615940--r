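#' Read a summary-statistics table
#'
#' Reads a delimited text table of per-variant two-sample summary
#' statistics.  Required header columns: `variant`, `beta_exposure`,
#' `se_exposure`, `beta_outcome`, `se_outcome`, `core` (0/1 or
#' TRUE/FALSE); extra columns are ignored and row order is preserved.
#' Tab delimiters are the default, with comma auto-detection from the
#' header line.  Inputs are assumed allele-harmonized.
#'
#' @param path file path.
#' @return A [summary_data] object.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
    else stopf("cannot detect delimiter (expected tab or comma): %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "#")
  needed <- c("variant", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome", "core")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stopf("missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (col in c("beta_exposure", "se_exposure", "beta_outcome",
                "se_outcome")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) stopf("non-numeric value in column '%s'", col)
    tab[[col]] <- v
  }
  if (any(tab$se_exposure <= 0))
    stopf("se_exposure must be strictly positive")
  if (any(tab$se_outcome <= 0))
    stopf("se_outcome must be strictly positive")
  core <- tab$core
  if (is.character(core)) core <- toupper(core) %in% c("1", "TRUE", "T")
  core <- as.logical(core)
  if (anyNA(core)) stopf("column 'core' must be 0/1 or TRUE/FALSE")
  if (!any(core)) stopf("no core variants flagged in 'core' column")
  summary_data(beta_x_hat = tab$beta_exposure, se_x = tab$se_exposure,
               beta_y_hat = tab$beta_outcome, se_y = tab$se_outcome,
               core = core, variant = tab$variant)
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_table()]; tab-delimited.
#'
#' @param data a [summary_data] object.
#' @param path output file path.
#' @export
write_summary_table <- function(data, path) {
  out <- data.frame(variant = data$variant,
                    beta_exposure = data$beta_x_hat,
                    se_exposure = data$se_x,
                    beta_outcome = data$beta_y_hat,
                    se_outcome = data$se_y,
                    core = as.integer(data$core))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes a human-readable report plus a machine-readable tab-delimited
#' block holding the point estimates, the selection statistic, the bias
#' estimate, and every requested confidence interval with its full
#' Monte-Carlo provenance (alpha split, gamma, b*, seed, draw count,
#' fallback flag).
#'
#' @param selection a `selection_result`.
#' @param intervals a list of `confidence_interval` objects.
#' @param path output file path.
#' @export
write_results <- function(selection, intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# focused instrument selection report")
  wl("# theta_core\t%.10g", selection$est_core$theta_hat)
  wl("# theta_full\t%.10g", selection$est_full$theta_hat)
  wl("# theta_focused\t%.10g", selection$theta_focused)
  wl("# selected\t%s", selection$selected)
  wl("# W_hat\t%.10g", selection$W_hat)
  wl("# amse_core\t%.10g", selection$amse_core)
  wl("# amse_full\t%.10g", selection$amse_full)
  wl("# b_hat\t%.10g", selection$bias$b_hat)
  wl("# delta_B_hat\t%.10g", selection$bias$delta_B_hat)
  wl(paste("method", "lower", "upper", "alpha", "alpha1", "alpha2",
           "gamma", "b_star", "n_draws", "seed", "fallback", sep = "\t"))
  for (iv in intervals) {
    wl("%s\t%.10g\t%.10g\t%g\t%g\t%g\t%g\t%g\t%d\t%d\t%s",
       iv$method, iv$lower, iv$upper, iv$alpha,
       iv$alpha1, iv$alpha2, iv$gamma, iv$b_star,
       as.integer(iv$n_draws), as.integer(iv$seed),
       iv$meta$fallback %||% "none")
  }
  invisible(path)
}

#' Parse a results report back into a data.frame of intervals
#'
#' @param path a report written by [write_results()].
#' @return A list with `header` (named numeric/character vector) and
#'   `intervals` (data.frame).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# \\S+\t", lines, value = TRUE)
  keys <- sub("^# (\\S+)\t.*$", "\\1", hdr)
  vals <- sub("^# \\S+\t", "", hdr)
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(header = stats::setNames(as.list(vals), keys), intervals = tab)
}
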