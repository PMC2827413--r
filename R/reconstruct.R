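#' Parallel-beam projection and filtered back-projection simulator
#'
#' Desk-scale stand-in for tomographic acquisition: each horizontal slice of
#' the input volume is forward-projected into a parallel-beam sinogram at
#' `n_angles` evenly spaced angles over 180 degrees and reconstructed by
#' Ram-Lak filtered back-projection. The output grid and spacing match the
#' input. The round trip introduces the mild ringing and streak artifacts of
#' real reconstructions, which downstream segmentation should tolerate.
#'
#' @param volume A [voxel_volume()].
#' @param n_angles Number of projection angles (>= 16).
#'
#' @return A [voxel_volume()] of the same shape and spacing.
#' @export
project_and_reconstruct <- function(volume, n_angles = 180L) {
  stopifnot(inherits(volume, "voxel_volume"))
  n_angles <- as.integer(n_angles)
  if (length(n_angles) != 1L || is.na(n_angles) || n_angles < 16L) {
    abort("`n_angles` must be a single integer >= 16.")
  }
  d <- dim(volume$grey)
  theta <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  out <- array(0, dim = d)
  geom <- slice_geometry(d[1], d[2], theta)
  for (k in seq_len(d[3])) {
    sino <- radon_slice(volume$grey[, , k], geom)
    out[, , k] <- fbp_slice(sino, geom)
  }
  out <- pmax(out, 0)
  voxel_volume(out, volume$spacing_mm,
               meta = c(volume$meta, list(reconstructed = TRUE, n_angles = n_angles)))
}

# precomputed geometry shared by all slices: centred pixel coordinates,
# detector bin count, per-angle detector positions of every pixel
slice_geometry <- function(n1, n2, theta) {
  cx <- (n1 + 1) / 2
  cy <- (n2 + 1) / 2
  xs <- rep(seq_len(n1) - cx, times = n2)
  ys <- rep(seq_len(n2) - cy, each = n1)
  nd <- 2L * ceiling(sqrt(max(abs(xs))^2 + max(abs(ys))^2)) + 3L
  tc <- (nd + 1) / 2
  # t-position of each pixel for each angle, as fractional detector index
  tpos <- lapply(theta, function(th) xs * cos(th) + ys * sin(th) + tc)
  list(n1 = n1, n2 = n2, nd = nd, theta = theta, tpos = tpos,
       ramp = ramp_kernel_fft(nd))
}

# frequency response of the discrete Ram-Lak ramp (Kak & Slaney band kernel),
# zero-padded to the FFT length used for circular-to-linear convolution
ramp_kernel_fft <- function(nd) {
  nfft <- 2^ceiling(log2(2 * nd))
  h <- numeric(nfft)
  h[1] <- 1 / 4
  n <- seq_len(nd)
  odd <- n[n %% 2 == 1]
  h[odd + 1] <- -1 / (pi^2 * odd^2)
  h[nfft - odd + 1] <- -1 / (pi^2 * odd^2)
  Re(fft(h))
}

# sinogram by linear splatting of pixel values onto detector bins
radon_slice <- function(img, geom) {
  v <- as.vector(img)
  sino <- matrix(0, geom$nd, length(geom$theta))
  for (j in seq_along(geom$theta)) {
    t <- geom$tpos[[j]]
    i0 <- floor(t)
    w <- t - i0
    sino[, j] <- tabulate_weighted(i0, v * (1 - w), geom$nd) +
      tabulate_weighted(i0 + 1L, v * w, geom$nd)
  }
  sino
}

tabulate_weighted <- function(bins, w, nbins) {
  s <- rowsum(w, bins)
  out <- numeric(nbins)
  out[as.integer(rownames(s))] <- s
  out
}

# Ram-Lak filtered back-projection of one sinogram
fbp_slice <- function(sino, geom) {
  nfft <- length(geom$ramp)
  rec <- numeric(geom$n1 * geom$n2)
  for (j in seq_along(geom$theta)) {
    p <- numeric(nfft)
    p[seq_len(geom$nd)] <- sino[, j]
    q <- Re(fft(fft(p) * geom$ramp, inverse = TRUE)) / nfft
    q <- q[seq_len(geom$nd)]
    t <- geom$tpos[[j]]
    i0 <- floor(t)
    w <- t - i0
    rec <- rec + q[i0] * (1 - w) + q[i0 + 1L] * w
  }
  matrix(rec * pi / length(geom$theta), geom$n1, geom$n2)
}
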