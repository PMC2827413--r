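#' Specification for a synthetic multi-experiment expression study
#'
#' Emulates the design of a three-experiment comparative transcriptome
#' study: a diurnal leaf time course and a tuber-induction series with two
#' biological replicates each, and a growing vs non-growing tuber comparison
#' with four replicates. Planted co-expression clusters follow per-condition
#' profile templates scaled by a log2 effect size; all other features are
#' flat. A stated fraction of each planted cluster is annotated
#' "transcription factor", and the first few members of each cluster are
#' flagged as marker genes (annotated "metabolism"), standing in for the
#' starch biosynthetic genes used to pick clusters of interest.
#'
#' @param n_features Total number of array features.
#' @param experiments Tibble with columns `experiment`, `conditions` (list
#'   column of character vectors) and `replicates` (>= 2 per condition).
#' @param planted_clusters List of planted clusters, each a list with
#'   `name`, `n_members`, `effect_log2` and `profiles` (named list:
#'   experiment -> numeric template in \[0, 1\] per condition).
#' @param tf_fraction_per_cluster Fraction of each planted cluster annotated
#'   "transcription factor" (in \[0, 1\]).
#' @param n_markers_per_cluster Cluster members flagged as marker genes.
#' @param noise_sd Log2-scale sd of multiplicative log-normal noise (>= 0).
#' @param baseline_intensity Intensity of an unexpressed feature (> 0).
#' @param seed Integer seed.
#'
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_features = 1000L,
                                experiments = default_experiments(),
                                planted_clusters = default_planted_clusters(),
                                tf_fraction_per_cluster = 0.06,
                                n_markers_per_cluster = 5L,
                                noise_sd = 0.25,
                                baseline_intensity = 100,
                                seed = 1L) {
  experiments <- as_tibble(experiments)
  stopifnot(all(c("experiment", "conditions", "replicates") %in% names(experiments)))
  if (any(experiments$replicates < 2L)) {
    abort("every experiment needs at least 2 replicates per condition.")
  }
  if (tf_fraction_per_cluster < 0 || tf_fraction_per_cluster > 1) {
    abort("`tf_fraction_per_cluster` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (baseline_intensity <= 0) abort("`baseline_intensity` must be > 0.")
  n_planted <- sum(vapply(planted_clusters, function(cl) cl$n_members, numeric(1)))
  if (n_planted > n_features) {
    abort("planted cluster members exceed `n_features`.")
  }
  for (cl in planted_clusters) {
    for (ex in seq_len(nrow(experiments))) {
      prof <- cl$profiles[[experiments$experiment[ex]]]
      if (is.null(prof) ||
          length(prof) != length(experiments$conditions[[ex]])) {
        abort(sprintf("cluster '%s' needs a profile of length %d for experiment '%s'.",
                      cl$name, length(experiments$conditions[[ex]]),
                      experiments$experiment[ex]))
      }
    }
  }
  structure(
    list(n_features = as.integer(n_features), experiments = experiments,
         planted_clusters = planted_clusters,
         tf_fraction_per_cluster = tf_fraction_per_cluster,
         n_markers_per_cluster = as.integer(n_markers_per_cluster),
         noise_sd = noise_sd, baseline_intensity = baseline_intensity,
         seed = as.integer(seed)),
    class = "expression_sim_spec"
  )
}

#' @rdname expression_sim_spec
#' @export
default_experiments <- function() {
  tibble(
    experiment = c("leaf_diurnal", "tuber_induction", "growth_velocity"),
    conditions = list(
      c("h0", "h4", "h8", "h12"),
      c("stage1", "stage3", "stage5"),
      c("growing", "nongrowing")
    ),
    replicates = c(2L, 2L, 4L)
  )
}

#' @rdname expression_sim_spec
#' @param effect_log2 Log2 effect size between the extreme conditions of
#'   each experiment (default 2, i.e. four-fold).
#' @param n_members Members per planted cluster.
#' @export
#' @details
#' The default plants five co-expression clusters, mirroring a five-cluster
#' K-means outcome in which marker genes (the starch-pathway stand-ins)
#' concentrate in three clusters: three "up" shapes carry markers
#' (`has_markers = TRUE`), a transient shape and a "down" shape do not.
#' Every cluster spans the full effect between the extreme conditions of
#' every experiment, so all members are differentially expressed under all
#' three conditions.
default_planted_clusters <- function(effect_log2 = 2, n_members = 30L) {
  mk <- function(name, leaf, induction, growth, has_markers) {
    list(name = name, n_members = as.integer(n_members),
         effect_log2 = effect_log2, has_markers = has_markers,
         profiles = list(leaf_diurnal = leaf, tuber_induction = induction,
                         growth_velocity = growth))
  }
  list(
    mk("ramp", c(0, 1 / 3, 2 / 3, 1), c(0, 0.5, 1), c(1, 0), TRUE),
    mk("early", c(0, 1, 1, 1), c(0, 1, 1), c(1, 0), TRUE),
    mk("late", c(0, 0, 0, 1), c(0, 0, 1), c(1, 0), TRUE),
    mk("transient", c(0, 1, 0, 1), c(0, 0.2, 1), c(1, 0), FALSE),
    mk("down", c(1, 2 / 3, 1 / 3, 0), c(1, 0.5, 0), c(0, 1), FALSE)
  )
}

#' Generate synthetic expression matrices with known ground truth
#'
#' Intensities are `baseline * 2^(effect * profile\[condition\])` with
#' multiplicative log-normal noise (`noise_sd` on the log2 scale);
#' non-planted features are flat at baseline. Sample columns are named
#' `<experiment>.<condition>.r<replicate>`.
#'
#' @param spec An [expression_sim_spec()].
#'
#' @return A list: `matrix` (features x all samples), `matrices` (named list
#'   of per-experiment column subsets), `design` (tibble: `sample`,
#'   `experiment`, `condition`, `replicate`), `annotation` (tibble:
#'   `feature`, `category`, `is_marker`), and `truth` (list: `planted`,
#'   `true_clusters`, `true_de` per experiment, `tf_features`, `markers`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  ex <- spec$experiments
  design <- purrr::pmap_dfr(ex, function(experiment, conditions, replicates) {
    tidyr::expand_grid(experiment = experiment, condition = conditions,
                       replicate = seq_len(replicates))
  })
  design$sample <- sprintf("%s.%s.r%d", design$experiment, design$condition,
                           design$replicate)
  design <- design[, c("sample", "experiment", "condition", "replicate")]

  features <- sprintf("feat_%04d", seq_len(spec$n_features))
  # log2 signal: planted members get effect * profile of their condition
  log2sig <- matrix(log2(spec$baseline_intensity),
                    nrow = spec$n_features, ncol = nrow(design),
                    dimnames = list(features, design$sample))
  cluster_of <- rep(NA_character_, spec$n_features)
  pos <- 0L
  for (cl in spec$planted_clusters) {
    rows <- pos + seq_len(cl$n_members)
    pos <- pos + cl$n_members
    cluster_of[rows] <- cl$name
    for (j in seq_len(nrow(design))) {
      prof <- cl$profiles[[design$experiment[j]]]
      cond_i <- match(design$condition[j],
                      ex$conditions[[match(design$experiment[j], ex$experiment)]])
      log2sig[rows, j] <- log2sig[rows, j] + cl$effect_log2 * prof[cond_i]
    }
  }
  withr::with_seed(derive_seed(spec$seed, "expression-noise"), {
    noise <- matrix(rnorm(length(log2sig), sd = spec$noise_sd),
                    nrow = nrow(log2sig))
  })
  mat <- 2^(log2sig + noise)

  planted <- features[!is.na(cluster_of)]
  # per-experiment truth: planted features whose profile is non-constant there
  true_de <- lapply(seq_len(nrow(ex)), function(i) {
    keep <- vapply(spec$planted_clusters, function(cl) {
      diff(range(cl$profiles[[ex$experiment[i]]])) > 0
    }, logical(1))
    names_keep <- vapply(spec$planted_clusters[keep], `[[`, character(1), "name")
    features[cluster_of %in% names_keep]
  })
  names(true_de) <- ex$experiment

  annotation <- build_annotation(spec, features, cluster_of)

  list(
    matrix = mat,
    matrices = lapply(setNames(ex$experiment, ex$experiment), function(e) {
      mat[, design$sample[design$experiment == e], drop = FALSE]
    }),
    design = design,
    annotation = annotation,
    truth = list(
      planted = planted,
      true_clusters = tibble(feature = planted,
                             cluster = cluster_of[!is.na(cluster_of)]),
      true_de = true_de,
      # co-regulated TFs: those planted in the marker-bearing clusters
      tf_features = annotation$feature[
        annotation$category == "transcription factor" &
          cluster_of %in% marker_cluster_names(spec)],
      tf_features_all = annotation$feature[
        annotation$category == "transcription factor" & !is.na(cluster_of)],
      markers = annotation$feature[annotation$is_marker]
    ),
    spec = spec
  )
}

marker_cluster_names <- function(spec) {
  keep <- vapply(spec$planted_clusters,
                 function(cl) isTRUE(cl$has_markers %||% TRUE), logical(1))
  vapply(spec$planted_clusters[keep], `[[`, character(1), "name")
}

build_annotation <- function(spec, features, cluster_of) {
  n <- length(features)
  category <- rep("unknown", n)
  is_marker <- rep(FALSE, n)
  withr::with_seed(derive_seed(spec$seed, "annotation"), {
    # background features: a realistic functional mix
    bg <- which(is.na(cluster_of))
    category[bg] <- sample(
      c("metabolism", "storage protein", "transcription factor", "unknown"),
      length(bg), replace = TRUE, prob = c(0.20, 0.05, 0.03, 0.72))
    for (cl in spec$planted_clusters) {
      rows <- which(cluster_of == cl$name)
      rest <- rows
      if (isTRUE(cl$has_markers %||% TRUE)) {
        n_mark <- min(spec$n_markers_per_cluster, length(rows))
        markers <- rows[seq_len(n_mark)]
        is_marker[markers] <- TRUE
        category[markers] <- "metabolism"
        rest <- setdiff(rows, markers)
      }
      n_tf <- round(spec$tf_fraction_per_cluster * length(rows))
      tf_rows <- head(rest, n_tf)
      category[tf_rows] <- "transcription factor"
      rest <- setdiff(rest, tf_rows)
      category[rest] <- sample(
        c("metabolism", "storage protein", "unknown"),
        length(rest), replace = TRUE, prob = c(0.45, 0.12, 0.43))
    }
  })
  tibble(feature = features, category = category, is_marker = is_marker)
}
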