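# independent oracles used across tests; these never call package internals

# literal Benjamini-Hochberg step-up selection: reject H_(1..k) for the
# largest k with p_(k) <= k/m * alpha
bh_select_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) / m * alpha)))
  sel <- logical(m)
  if (k > 0) sel[o[seq_len(k)]] <- TRUE
  sel
}

# brute-force BH adjusted p-values: running minimum of p_(i) * m / i from the top
bh_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ps))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# analytic sphere voxel count oracle: centres strictly inside radius r around c
sphere_voxel_count <- function(center, r, shape) {
  xs <- seq_len(shape[1]); ys <- seq_len(shape[2]); zs <- seq_len(shape[3])
  sum(outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
            (zs - center[3])^2, `+`) <= r^2)
}

# tiny two-population phantom helper: one centred sphere, configurable noise
sphere_phantom <- function(radius, n = 2 * radius + 9, spacing_mm = 1,
                           grey_sd = 0, soil_sd = grey_sd, blur_sigma = 0,
                           seed = 1) {
  generate_phantom(phantom_spec(
    shape = rep(n, 3), spacing_mm = spacing_mm,
    tubers = list(tuber_spec(rep((n + 1) / 2, 3), rep(radius, 3),
                             grey_sd = grey_sd)),
    soil_grey_sd = soil_sd, blur_sigma = blur_sigma, seed = seed
  ))
}

# planted-profile matrix for clustering tests: sinusoid / ramp / step groups
planted_profile_matrix <- function(n_per_group = 50, n_samples = 12,
                                   noise_sd = 0.2, seed = 1) {
  t <- seq_len(n_samples)
  # step rises at the first quartile so the three shapes are mutually
  # distinguishable (a half-split step is nearly collinear with the ramp)
  templates <- rbind(
    sin(2 * pi * t / n_samples),
    (t - 1) / (n_samples - 1),
    rep(c(0, 1), c(ceiling(n_samples / 4), n_samples - ceiling(n_samples / 4)))
  )
  withr::with_seed(seed, {
    x <- templates[rep(1:3, each = n_per_group), ] +
      matrix(rnorm(3 * n_per_group * n_samples, sd = noise_sd),
             nrow = 3 * n_per_group)
  })
  rownames(x) <- sprintf("g%d_f%02d", rep(1:3, each = n_per_group),
                         rep(seq_len(n_per_group), 3))
  colnames(x) <- sprintf("s%02d", t)
  list(x = x, truth = rep(1:3, each = n_per_group))
}

# default three-experiment selection chain used by end-to-end tests
run_selection_chain <- function(sim, fc_cutoff = 2, alpha = 0.05, k = 5,
                                cluster_seed = 1) {
  norm <- normalize_expression(sim$matrix)
  pairs <- list(leaf_diurnal = c("h0", "h12"),
                tuber_induction = c("stage1", "stage5"),
                growth_velocity = c("nongrowing", "growing"))
  de <- lapply(names(pairs), function(e) {
    select_differential(norm, sim$design, e, pair = pairs[[e]],
                        fc_cutoff = fc_cutoff, alpha = alpha)
  })
  names(de) <- names(pairs)
  venn <- intersect_feature_sets(de)
  out <- list(norm = norm, de = de, venn = venn)
  if (length(venn$common) >= k) {
    out$clusters <- cluster_profiles(norm, k = k, seed = cluster_seed,
                                     features = venn$common)
    mk <- intersect(sim$truth$markers, venn$common)
    if (length(mk)) {
      out$candidates <- extract_tf_candidates(out$clusters, sim$annotation, mk)
    }
  }
  out
}
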