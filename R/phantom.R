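#' Voxel volume container
#'
#' A reconstructed CT volume: a 3D grid of grey levels (16-bit scale) with an
#' isotropic physical voxel spacing. The third array dimension is vertical.
#'
#' @param grey Numeric 3D array of grey levels (all values >= 0).
#' @param spacing_mm Voxel edge length in millimetres (isotropic, > 0).
#' @param meta Optional named list of free-form acquisition metadata.
#'
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grey, spacing_mm, meta = list()) {
  if (!is.array(grey) || length(dim(grey)) != 3L) {
    abort("`grey` must be a 3D array.")
  }
  if (any(grey < 0)) abort("grey levels must be >= 0.")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    abort("`spacing_mm` must be a single positive number.")
  }
  structure(
    list(grey = grey, spacing_mm = spacing_mm, meta = meta),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grey)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.4g mm, grey range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing_mm, min(x$grey), max(x$grey)
  ))
  invisible(x)
}

#' Tuber specification for phantom construction
#'
#' Describes one synthetic tuber as an ellipsoid in voxel coordinates with a
#' grey-level population. The orientation rotates the first two semi-axes
#' about the vertical axis.
#'
#' @param center Numeric length-3 voxel coordinates of the ellipsoid centre.
#' @param semi_axes Numeric length-3 positive semi-axis lengths in voxels.
#' @param orientation_deg Rotation about the vertical axis, degrees.
#' @param grey_mean,grey_sd Tuber grey-level mean and noise sd (16-bit scale).
#'   The default mean 3450 sits at the centre of the standard segmentation
#'   window \[2938, 3963\].
#'
#' @return A `tuber_spec` list.
#' @export
tuber_spec <- function(center, semi_axes, orientation_deg = 0,
                       grey_mean = 3450, grey_sd = 50) {
  if (length(center) != 3L || length(semi_axes) != 3L) {
    abort("`center` and `semi_axes` must have length 3.")
  }
  if (any(semi_axes <= 0)) abort("`semi_axes` must all be positive.")
  if (grey_mean < 0 || grey_mean > 65535) {
    abort("`grey_mean` must lie in the representable 16-bit range [0, 65535].")
  }
  if (grey_sd < 0) abort("`grey_sd` must be >= 0.")
  structure(
    list(
      center = as.numeric(center), semi_axes = as.numeric(semi_axes),
      orientation_deg = as.numeric(orientation_deg),
      grey_mean = as.numeric(grey_mean), grey_sd = as.numeric(grey_sd)
    ),
    class = "tuber_spec"
  )
}

#' Phantom specification
#'
#' Scene description for a synthetic soil-embedded tuber scan: grid size,
#' physical spacing, soil and tuber grey populations, partial-volume blur and
#' a seed. The default spacing 0.141 mm matches the scan resolution of the
#' CT protocol the package emulates; the default soil mean 2426 places the
#' lower segmentation threshold 2938 midway between the soil and tuber
#' populations.
#'
#' @param shape Integer length-3 grid dimensions in voxels (each >= 8).
#' @param spacing_mm Voxel edge length in mm (> 0).
#' @param tubers List of [tuber_spec()] objects (may be empty).
#' @param soil_grey_mean,soil_grey_sd Background grey population.
#' @param blur_sigma Gaussian partial-volume smoothing width in voxels (>= 0).
#' @param seed Integer seed controlling all phantom noise.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, spacing_mm = 0.141, tubers = list(),
                         soil_grey_mean = 2426, soil_grey_sd = 50,
                         blur_sigma = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    abort("`shape` must be three grid dimensions, each >= 8 voxels.")
  }
  if (spacing_mm <= 0) abort("`spacing_mm` must be > 0.")
  if (blur_sigma < 0) abort("`blur_sigma` must be >= 0.")
  if (inherits(tubers, "tuber_spec")) tubers <- list(tubers)
  ok <- vapply(tubers, inherits, logical(1), "tuber_spec")
  if (!all(ok)) abort("`tubers` must be a list of tuber_spec objects.")
  structure(
    list(
      shape = shape, spacing_mm = spacing_mm, tubers = tubers,
      soil_grey_mean = soil_grey_mean, soil_grey_sd = soil_grey_sd,
      blur_sigma = blur_sigma, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# axis-aligned extent of an ellipsoid rotated about the vertical axis
ellipsoid_extent <- function(tub) {
  th <- tub$orientation_deg * pi / 180
  a <- tub$semi_axes[1]; b <- tub$semi_axes[2]
  c(
    sqrt((a * cos(th))^2 + (b * sin(th))^2),
    sqrt((a * sin(th))^2 + (b * cos(th))^2),
    tub$semi_axes[3]
  )
}

# logical membership over the full grid, evaluated on a bounding box only
ellipsoid_mask <- function(tub, shape) {
  ext <- ellipsoid_extent(tub)
  lo <- pmax(1L, floor(tub$center - ext - 1))
  hi <- pmin(shape, ceiling(tub$center + ext + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  th <- tub$orientation_deg * pi / 180
  a <- tub$semi_axes[1]; b <- tub$semi_axes[2]; cc <- tub$semi_axes[3]
  dx <- outer(xs - tub$center[1], rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - tub$center[2])
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  # membership scaled by (abc)^2 to keep boundary voxels (e.g. integer
  # lattice points exactly on a sphere) numerically inclusive
  plane <- (u * b * cc)^2 + (v * a * cc)^2
  rhs0 <- (a * b * cc)^2
  sub <- array(FALSE, dim = c(length(xs), length(ys), length(zs)))
  for (k in seq_along(zs)) {
    w <- (zs[k] - tub$center[3]) * a * b
    sub[, , k] <- plane <= rhs0 - w^2 + 1e-9 * rhs0
  }
  box <- array(FALSE, dim = shape)
  box[xs, ys, zs] <- sub
  box
}

# separable Gaussian blur with edge-renormalized band kernels
gaussian_blur3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- g[keep]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  # dim 1
  a <- array(band(d[1]) %*% matrix(a, d[1]), dim = d)
  # dim 2
  a <- aperm(array(band(d[2]) %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   dim = d[c(2, 1, 3)]), c(2, 1, 3))
  # dim 3
  a <- aperm(array(band(d[3]) %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                   dim = d[c(3, 1, 2)]), c(2, 3, 1))
  a
}

#' Generate a soil-embedded tuber phantom with ground truth
#'
#' Builds a grey-level volume in which voxels whose centres fall inside a
#' tuber ellipsoid carry that tuber's grey mean and all others the soil mean;
#' Gaussian partial-volume blur and additive grey noise are then applied.
#' Ground-truth labels and analytic volumes are computed before blur and
#' noise, so they are exact.
#'
#' @param spec A [phantom_spec()].
#'
#' @return A list with elements `volume` (a [voxel_volume()]) and `truth`,
#'   itself a list with `labels` (integer 3D array, 0 = soil), and `volumes`,
#'   a tibble with one row per tuber: `label`, `voxel_count` (voxels whose
#'   centre lies inside the ellipsoid), `volume_cm3` (analytic
#'   4/3 pi abc spacing^3) and `centroid_*`.
#' @export
#' @examples
#' sp <- phantom_spec(shape = c(32, 32, 32), spacing_mm = 1,
#'                    tubers = tuber_spec(c(16, 16, 16), c(10, 10, 10)))
#' ph <- generate_phantom(sp)
#' ph$truth$volumes$volume_cm3  # 4/3*pi*10^3 mm^3 = 4.18879 cm^3
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  labels <- array(0L, dim = shape)
  rows <- vector("list", length(spec$tubers))
  for (i in seq_along(spec$tubers)) {
    tub <- spec$tubers[[i]]
    ext <- ellipsoid_extent(tub)
    if (any(tub$center - ext < 1) || any(tub$center + ext > shape)) {
      abort(sprintf("tuber %d extends outside the grid.", i))
    }
    m <- ellipsoid_mask(tub, shape)
    if (any(labels[m] != 0L)) {
      abort(sprintf("tuber %d overlaps an earlier tuber; ground truth would be ambiguous.", i))
    }
    labels[m] <- i
    idx <- which(m, arr.ind = TRUE)
    rows[[i]] <- tibble(
      label = i,
      voxel_count = nrow(idx),
      volume_cm3 = 4 / 3 * pi * prod(tub$semi_axes) * (spec$spacing_mm / 10)^3,
      centroid_x = mean(idx[, 1]), centroid_y = mean(idx[, 2]),
      centroid_z = mean(idx[, 3])
    )
  }
  volumes <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(label = integer(), voxel_count = integer(), volume_cm3 = double(),
           centroid_x = double(), centroid_y = double(), centroid_z = double())

  grey <- array(spec$soil_grey_mean, dim = shape)
  sdfield <- array(spec$soil_grey_sd, dim = shape)
  for (i in seq_along(spec$tubers)) {
    sel <- labels == i
    grey[sel] <- spec$tubers[[i]]$grey_mean
    sdfield[sel] <- spec$tubers[[i]]$grey_sd
  }
  grey <- gaussian_blur3d(grey, spec$blur_sigma)
  withr::with_seed(derive_seed(spec$seed, "phantom-noise"), {
    if (any(sdfield > 0)) {
      grey <- grey + rnorm(length(grey), sd = as.vector(sdfield))
    }
  })
  grey <- pmin(pmax(grey, 0), 65535)

  list(
    volume = voxel_volume(array(grey, dim = shape), spec$spacing_mm,
                          meta = list(seed = spec$seed, kind = "synthetic phantom")),
    truth = list(labels = labels, volumes = volumes)
  )
}
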