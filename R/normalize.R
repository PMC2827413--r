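#' Three-step microarray normalization
#'
#' The classic GeneSpring-style recipe: (1) intensities below `floor` are
#' raised to `floor`; (2) each chip (sample column) is divided by its
#' post-floor percentile (the 50th, i.e. the median, by default); (3) each
#' feature row is divided by its median across all samples of the dataset.
#' After step 3 every feature's median across the dataset is 1, so profiles
#' from different experiments are comparable.
#'
#' @param raw Non-negative numeric matrix, features x samples, with
#'   dimnames.
#' @param floor Intensity floor (> 0, default 5).
#' @param chip_percentile Per-chip scaling percentile in (0, 100\];
#'   default 50.
#' @param center_features Apply step 3 (default `TRUE`); `FALSE` stops
#'   after per-chip scaling.
#'
#' @return A `normalized_expr` object: list with `values` (normalized
#'   matrix) and `provenance` (floor, percentile, per-chip scale factors,
#'   per-feature centering medians, dataset = the sample set the step-3
#'   median was taken over).
#' @export
#' @examples
#' m <- matrix(c(3, 10, 20, 40, 100), ncol = 1,
#'             dimnames = list(paste0("f", 1:5), "chip1"))
#' step2 <- normalize_expression(m)$provenance$chip_scale  # P50 = 20
normalize_expression <- function(raw, floor = 5, chip_percentile = 50,
                                 center_features = TRUE) {
  if (!is.matrix(raw) || !is.numeric(raw)) abort("`raw` must be a numeric matrix.")
  if (length(raw) == 0) abort("`raw` is empty.")
  if (any(raw < 0)) abort("intensities must be >= 0.")
  if (floor <= 0) abort("`floor` must be > 0.")
  if (chip_percentile <= 0 || chip_percentile > 100) {
    abort("`chip_percentile` must lie in (0, 100].")
  }
  v <- pmax(raw, floor)
  chip_scale <- apply(v, 2, quantile, probs = chip_percentile / 100, names = FALSE)
  if (any(chip_scale == 0)) {
    abort(sprintf("chip(s) %s have a zero scaling percentile.",
                  paste(colnames(v)[chip_scale == 0], collapse = ", ")))
  }
  v <- sweep(v, 2, chip_scale, `/`)
  if (center_features) {
    feature_median <- apply(v, 1, median)
    v <- sweep(v, 1, feature_median, `/`)
  } else {
    feature_median <- rep(1, nrow(v))
  }
  structure(
    list(
      values = v,
      provenance = list(floor = floor, chip_percentile = chip_percentile,
                        chip_scale = chip_scale,
                        feature_median = feature_median,
                        dataset = colnames(raw))
    ),
    class = "normalized_expr"
  )
}

#' @export
print.normalized_expr <- function(x, ...) {
  cat(sprintf(
    "<normalized_expr> %d features x %d samples (floor %g, chip P%g, per-feature median centred)\n",
    nrow(x$values), ncol(x$values), x$provenance$floor,
    x$provenance$chip_percentile))
  invisible(x)
}

norm_values <- function(x) {
  if (inherits(x, "normalized_expr")) x$values
  else if (is.matrix(x)) x
  else abort("expected a `normalized_expr` or a numeric matrix.")
}
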