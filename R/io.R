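#' Read and write voxel volumes as multi-page 16-bit TIFF stacks
#'
#' One TIFF page per horizontal slice, grey levels on the 16-bit scale,
#' with a JSON sidecar (`<path>.json`) recording `spacing_mm`, `shape` and
#' any metadata. Label masks use the same container.
#'
#' @param volume A [voxel_volume()] (grey levels in \[0, 65535\]).
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#'
#' @return `write_volume_tiff()` returns `path` invisibly;
#'   `read_volume_tiff()` returns a [voxel_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  g <- round(volume$grey)
  if (any(g > 65535)) abort("grey levels exceed the 16-bit range.")
  pages <- lapply(seq_len(dim(g)[3]), function(k) g[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(spacing_mm = volume$spacing_mm, shape = dim(g), meta = volume$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) g[, , k] <- pages[[k]]
  voxel_volume(g, side$spacing_mm, meta = as.list(side$meta))
}

#' Read and write feature-by-sample matrices as TSV
#'
#' Rows are features (first column `feature`), columns samples.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path TSV path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` a numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- as_tibble(mat, rownames = "feature")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
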