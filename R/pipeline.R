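#' Simulate a volumetry validation campaign
#'
#' One spherical single-tuber phantom per requested true volume, each on a
#' grid just large enough for the tuber plus blur margin — the synthetic
#' counterpart of scanning a set of tubers of known volume to validate
#' voxel-counting volumetry.
#'
#' @param true_volumes_cm3 Target tuber volumes (cm^3, > 0).
#' @param spacing_mm Voxel spacing (mm).
#' @param blur_sigma Partial-volume blur (voxels).
#' @param grey_sd Grey noise sd applied to both populations.
#' @param seed Integer seed.
#'
#' @return A list of [generate_phantom()] results, one per tuber, plus an
#'   attribute-free `truth` tibble binding each phantom's analytic volume.
#' @export
simulate_volumetry_campaign <- function(true_volumes_cm3, spacing_mm = 1,
                                        blur_sigma = 1, grey_sd = 50,
                                        seed = 1L) {
  if (any(true_volumes_cm3 <= 0)) abort("volumes must be > 0.")
  purrr::imap(true_volumes_cm3, function(v, i) {
    r <- (3 * v * 1000 / (4 * pi))^(1 / 3) / spacing_mm  # radius in voxels
    margin <- ceiling(4 * blur_sigma + 4)
    n <- 2L * ceiling(r + margin) + 1L
    ctr <- rep((n + 1) / 2, 3)
    generate_phantom(phantom_spec(
      shape = rep(n, 3), spacing_mm = spacing_mm,
      tubers = list(tuber_spec(ctr, rep(r, 3), grey_sd = grey_sd)),
      soil_grey_sd = grey_sd, blur_sigma = blur_sigma,
      seed = derive_seed(seed, paste0("campaign-", i))
    ))
  })
}

#' Build a validated pipeline configuration
#'
#' Central run configuration with the standard defaults of the workflow
#' this package implements: segmentation window \[2938, 3963\], intensity
#' floor 5, 50th-percentile chip scaling, two-fold volcano cutoff at alpha
#' 0.05, five K-means clusters, growth thresholds 0.1 cm^3/day absolute
#' and 0.01/day relative. Any field can be overridden; the structure is
#' validated and violations are reported with their field path.
#'
#' @param ... Named overrides, nested lists matching the config tree (see
#'   the default returned by `run_config()`).
#' @param config Optional list (e.g. from `yaml::read_yaml()`) merged
#'   before `...`.
#'
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., config = NULL) {
  base <- list(
    seed = 1L,
    imaging = list(
      enabled = TRUE, n_tubers = 4L, n_timepoints = 4L, dt_days = 2,
      initial_volumes_cm3 = NULL, velocities_cm3_per_day = NULL,
      spacing_mm = 1, blur_sigma = 1, grey_sd = 50,
      reconstruct = FALSE, n_angles = 90L,
      window = list(lower = 2938, upper = 3963),
      min_voxels = 64L, max_disp = 10,
      abs_threshold = 0.1, rel_threshold = 0.01
    ),
    expression = list(
      enabled = TRUE, n_features = 1000L, noise_sd = 0.25, effect_log2 = 2,
      floor = 5, chip_percentile = 50, fc_cutoff = 2, alpha = 0.05,
      k = 5L, n_init = 25L,
      pairs = list(leaf_diurnal = c("h0", "h12"),
                   tuber_induction = c("stage1", "stage5"),
                   growth_velocity = c("nongrowing", "growing"))
    ),
    qpcr = list(
      enabled = TRUE,
      true_ratios = list(GBSS = 4, GPT2 = 2.5, Susy4 = 8),
      efficiency_target = 1.95, efficiency_reference = 2,
      jitter_sd = 0.1, n_technical = 3L
    )
  )
  cfg <- modify_deep(base, config %||% list())
  cfg <- modify_deep(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

modify_deep <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) && !is.null(names(upd[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  fail <- function(path, msg) abort(sprintf("config field `%s`: %s", path, msg))
  chk_num <- function(x, path, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) fail(path, "must be a number")
    if (x < lo || x > hi) fail(path, sprintf("must be in [%s, %s]", lo, hi))
  }
  chk_num(cfg$seed, "seed")
  im <- cfg$imaging
  if (isTRUE(im$enabled)) {
    chk_num(im$n_tubers, "imaging.n_tubers", 1)
    chk_num(im$n_timepoints, "imaging.n_timepoints", 2)
    chk_num(im$dt_days, "imaging.dt_days", 1e-9)
    chk_num(im$spacing_mm, "imaging.spacing_mm", 1e-9)
    chk_num(im$blur_sigma, "imaging.blur_sigma", 0)
    chk_num(im$grey_sd, "imaging.grey_sd", 0)
    chk_num(im$window$lower, "imaging.window.lower", 0, 65535)
    chk_num(im$window$upper, "imaging.window.upper", 0, 65535)
    if (im$window$lower > im$window$upper) {
      fail("imaging.window", "lower must be <= upper")
    }
    chk_num(im$min_voxels, "imaging.min_voxels", 1)
    chk_num(im$max_disp, "imaging.max_disp", 1e-9)
    if (isTRUE(im$reconstruct)) chk_num(im$n_angles, "imaging.n_angles", 16)
    chk_num(im$abs_threshold, "imaging.abs_threshold", 0)
    chk_num(im$rel_threshold, "imaging.rel_threshold", 0)
  }
  expr <- cfg$expression
  if (isTRUE(expr$enabled)) {
    chk_num(expr$n_features, "expression.n_features", 10)
    chk_num(expr$noise_sd, "expression.noise_sd", 0)
    chk_num(expr$floor, "expression.floor", 1e-9)
    chk_num(expr$chip_percentile, "expression.chip_percentile", 1e-9, 100)
    chk_num(expr$fc_cutoff, "expression.fc_cutoff", 1)
    chk_num(expr$alpha, "expression.alpha", 1e-12, 1)
    chk_num(expr$k, "expression.k", 1)
    chk_num(expr$n_init, "expression.n_init", 1)
  }
  qp <- cfg$qpcr
  if (isTRUE(qp$enabled)) {
    chk_num(qp$efficiency_target, "qpcr.efficiency_target", 1 + 1e-9, 2)
    chk_num(qp$efficiency_reference, "qpcr.efficiency_reference", 1 + 1e-9, 2)
    chk_num(qp$jitter_sd, "qpcr.jitter_sd", 0)
    chk_num(qp$n_technical, "qpcr.n_technical", 1)
  }
  invisible(cfg)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' phantom campaign -> (optional reconstruction) -> segmentation -> volume
#' measurement -> tracking -> growth velocity; expression simulation ->
#' normalization -> per-experiment differential selection -> intersection
#' -> clustering -> functional summary -> TF candidates; qPCR simulation ->
#' Pfaffl ratios. All outputs are plain TSV/JSON under `out_dir`, and a
#' `manifest.json` records the configuration, its hash, package and R
#' versions and a content hash per output file. Rerunning with the same
#' config and seed reproduces identical outputs.
#'
#' @param config A [run_config()] (or list coercible through it).
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, a list of the in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run_")) {
  if (!inherits(config, "run_config")) config <- run_config(config = config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  if (isTRUE(config$imaging$enabled)) {
    results$imaging <- pipeline_imaging(config, file.path(out_dir, "imaging"))
  }
  if (isTRUE(config$expression$enabled)) {
    results$expression <- pipeline_expression(config, file.path(out_dir, "expression"))
  }
  if (isTRUE(config$qpcr$enabled)) {
    results$qpcr <- pipeline_qpcr(config, file.path(out_dir, "qpcr"))
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("tubertools")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = lapply(setNames(files, files), function(f) {
      rlang::hash(readBin(file.path(out_dir, f), "raw",
                          file.size(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

pipeline_imaging <- function(config, dir) {
  im <- config$imaging
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- im$n_tubers
  v0 <- im$initial_volumes_cm3 %||% seq(0.5, 2.5, length.out = n)
  vel <- im$velocities_cm3_per_day %||%
    ifelse(seq_len(n) %% 2 == 1, seq(0.2, 0.5, length.out = n), 0)
  times <- (seq_len(im$n_timepoints) - 1) * im$dt_days
  radius_vox <- function(v) (3 * v * 1000 / (4 * pi))^(1 / 3) / im$spacing_mm
  r_max <- radius_vox(v0 + pmax(vel, 0) * max(times))
  margin <- ceiling(4 * im$blur_sigma + 5)
  xc <- cumsum(2 * ceiling(r_max) + margin) - ceiling(r_max)
  nx <- ceiling(max(xc + r_max)) + margin
  ny <- 2L * ceiling(max(r_max)) + 2L * margin
  truth_rows <- list()
  masks <- vector("list", length(times))
  for (ti in seq_along(times)) {
    vols <- v0 + vel * times[ti]
    tubers <- lapply(seq_len(n), function(i) {
      tuber_spec(c(xc[i], ny / 2, ny / 2), rep(radius_vox(vols[i]), 3),
                 grey_sd = im$grey_sd)
    })
    ph <- generate_phantom(phantom_spec(
      shape = c(nx, ny, ny), spacing_mm = im$spacing_mm, tubers = tubers,
      soil_grey_sd = im$grey_sd, blur_sigma = im$blur_sigma,
      seed = derive_seed(config$seed, paste0("imaging-t", ti))
    ))
    vol <- ph$volume
    if (isTRUE(im$reconstruct)) {
      vol <- project_and_reconstruct(vol, im$n_angles)
    }
    masks[[ti]] <- segment_tubers(vol, im$window$lower, im$window$upper,
                                  im$min_voxels)
    truth_rows[[ti]] <- dplyr::mutate(ph$truth$volumes, time_days = times[ti])
  }
  tracked <- track_tubers(masks, max_disp = im$max_disp, times = times)
  tracked$volume_cm3 <- tracked$voxel_count * (im$spacing_mm / 10)^3
  fit <- estimate_velocity(tracked, abs_threshold = im$abs_threshold,
                           rel_threshold = im$rel_threshold)
  truth <- dplyr::bind_rows(truth_rows)
  readr::write_tsv(tracked, file.path(dir, "volumes.tsv"))
  readr::write_tsv(tidy(fit), file.path(dir, "velocity.tsv"))
  readr::write_tsv(truth, file.path(dir, "true_volumes.tsv"))
  list(tracked = tracked, fit = fit, truth = truth)
}

pipeline_expression <- function(config, dir) {
  ex <- config$expression
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_expression(expression_sim_spec(
    n_features = ex$n_features, noise_sd = ex$noise_sd,
    planted_clusters = default_planted_clusters(effect_log2 = ex$effect_log2),
    seed = derive_seed(config$seed, "expression")
  ))
  norm <- normalize_expression(sim$matrix, floor = ex$floor,
                               chip_percentile = ex$chip_percentile)
  de <- lapply(setNames(names(ex$pairs), names(ex$pairs)), function(e) {
    select_differential(norm, sim$design, e, pair = ex$pairs[[e]],
                        fc_cutoff = ex$fc_cutoff, alpha = ex$alpha)
  })
  venn <- intersect_feature_sets(de)
  clusters <- NULL
  markers <- intersect(sim$truth$markers, venn$common)
  candidates <- tibble(feature = character(), cluster = integer(),
                       correlation_to_markers = double())
  selected <- tibble(cluster = integer(), n_markers = integer(),
                     n_features = integer())
  if (length(venn$common) >= ex$k) {
    clusters <- cluster_profiles(norm, k = ex$k, n_init = ex$n_init,
                                 seed = derive_seed(config$seed, "cluster"),
                                 features = venn$common)
    candidates <- extract_tf_candidates(clusters, sim$annotation, markers)
    if (length(markers)) {
      selected <- suppressWarnings(select_clusters(clusters, markers))
    }
  }
  summary_features <- if (nrow(selected) && !is.null(clusters)) {
    names(clusters$assignment)[clusters$assignment %in% selected$cluster]
  } else venn$common
  fun_summary <- if (length(summary_features)) {
    summarize_function(summary_features, sim$annotation)
  } else tibble(category = character(), count = integer(), percent = double())
  write_matrix_tsv(norm$values, file.path(dir, "normalized.tsv"))
  for (e in names(de)) {
    readr::write_tsv(as_tibble(de[[e]]), file.path(dir, paste0("de_", e, ".tsv")))
  }
  jsonlite::write_json(
    list(common = venn$common, regions = venn$regions),
    file.path(dir, "venn.json"), auto_unbox = TRUE, digits = NA)
  cluster_tbl <- if (is.null(clusters)) {
    tibble(feature = character(), cluster = integer())
  } else tidy(clusters)
  readr::write_tsv(cluster_tbl, file.path(dir, "clusters.tsv"))
  readr::write_tsv(fun_summary, file.path(dir, "function_summary.tsv"))
  readr::write_tsv(candidates, file.path(dir, "tf_candidates.tsv"))
  list(sim = sim, norm = norm, de = de, venn = venn, clusters = clusters,
       selected = selected, fun_summary = fun_summary, candidates = candidates)
}

pipeline_qpcr <- function(config, dir) {
  qp <- config$qpcr
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_qpcr(
    unlist(qp$true_ratios),
    efficiency_target = qp$efficiency_target,
    efficiency_reference = qp$efficiency_reference,
    jitter_sd = qp$jitter_sd, n_technical = qp$n_technical,
    seed = derive_seed(config$seed, "qpcr")
  )
  ratios <- pfaffl_ratio(sim$ct)
  readr::write_tsv(sim$ct, file.path(dir, "ct.tsv"))
  readr::write_tsv(ratios, file.path(dir, "ratios.tsv"))
  list(sim = sim, ratios = ratios)
}
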