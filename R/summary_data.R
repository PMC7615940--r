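#' Two-sample summary statistics with core-instrument membership
#'
#' Container for per-variant GWAS summary statistics used throughout the
#' package: the variant-exposure association estimate and its standard
#' error, the variant-outcome association estimate and its standard error,
#' and a flag marking membership of the core set of trusted instruments.
#' Exposure and outcome associations are assumed to come from two
#' non-overlapping samples, so all `2p` estimates are mutually independent
#' normals with known standard errors, and alleles are assumed
#' pre-harmonized.
#'
#' @param beta_x_hat numeric vector of exposure association estimates.
#' @param se_x numeric vector of their standard errors (strictly positive).
#' @param beta_y_hat numeric vector of outcome association estimates.
#' @param se_y numeric vector of their standard errors (strictly positive).
#' @param core logical vector: `TRUE` for variants in the core set.
#' @param variant optional character vector of variant labels.
#'
#' @return An object of class `summary_data`: a `data.frame` with columns
#'   `variant`, `beta_x_hat`, `se_x`, `beta_y_hat`, `se_y`, `core`.
#' @examples
#' d <- summary_data(beta_x_hat = c(0.2, 0.21), se_x = c(0.03, 0.03),
#'                   beta_y_hat = c(0.04, 0.05), se_y = c(0.03, 0.03),
#'                   core = c(TRUE, FALSE))
#' core_idx(d)
#' @export
summary_data <- function(beta_x_hat, se_x, beta_y_hat, se_y, core,
                         variant = NULL) {
  p <- length(beta_x_hat)
  if (p < 2L) stopf("need at least 2 variants, got %d", p)
  lens <- c(length(se_x), length(beta_y_hat), length(se_y), length(core))
  if (any(lens != p))
    stopf("all per-variant vectors must have length %d", p)
  check_finite_numeric(beta_x_hat, "beta_x_hat")
  check_finite_numeric(beta_y_hat, "beta_y_hat")
  check_finite_numeric(se_x, "se_x")
  check_finite_numeric(se_y, "se_y")
  if (any(se_x <= 0)) stopf("se_x must be strictly positive")
  if (any(se_y <= 0)) stopf("se_y must be strictly positive")
  core <- as.logical(core)
  if (anyNA(core)) stopf("'core' must be logical without NA")
  if (!any(core)) stopf("no core variants: at least one 'core' flag must be TRUE")
  if (all(core)) stopf("all variants are core: at least one must be additional")
  if (is.null(variant)) variant <- paste0("v", seq_len(p))
  variant <- as.character(variant)
  out <- data.frame(variant = variant, beta_x_hat = beta_x_hat,
                    se_x = se_x, beta_y_hat = beta_y_hat, se_y = se_y,
                    core = core, stringsAsFactors = FALSE)
  class(out) <- c("summary_data", "data.frame")
  out
}

#' @rdname summary_data
#' @param x a `summary_data` object.
#' @export
core_idx <- function(x) which(x$core)

#' @rdname summary_data
#' @export
add_idx <- function(x) which(!x$core)

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf("summary_data: %d variants (%d core, %d additional)\n",
              nrow(x), sum(x$core), sum(!x$core)))
  NextMethod()
}

# Restrict to core variants plus a chosen subset of additional variants.
# `add_subset` holds row indices (into x) of additional variants to keep.
subset_additional <- function(x, add_subset) {
  keep <- sort(unique(c(which(x$core), as.integer(add_subset))))
  out <- x[keep, , drop = FALSE]
  class(out) <- c("summary_data", "data.frame")
  rownames(out) <- NULL
  out
}
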