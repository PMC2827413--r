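#' Correlation-distance K-means clustering of expression profiles
#'
#' Each feature's profile is standardized (z-scored) across samples, after
#' which Euclidean K-means is equivalent to clustering under Pearson
#' correlation distance `d = 1 - r` (up to a monotone transform). The best
#' of `n_init` seeded restarts by within-cluster sum of squares is kept, so
#' the result is deterministic given `seed`. The default `k = 5` is the
#' cluster count used in the comparative starch-pathway analysis this
#' package reproduces.
#'
#' @param x Numeric matrix (features x samples) of profiles to cluster —
#'   typically the normalized values of the intersected feature set — or a
#'   `normalized_expr` (optionally subset with `features`).
#' @param k Number of clusters (default 5; must not exceed the number of
#'   features).
#' @param n_init Number of random restarts (default 25).
#' @param seed Integer seed.
#' @param features Optional character vector of rows to cluster.
#'
#' @return A `coexpr_clusters` object: `assignment` (named integer),
#'   `centroids` (k x samples, standardized scale), `inertia` (total
#'   within-cluster sum of squares), `sizes`, `z` (the standardized
#'   matrix). `tidy()` gives a feature/cluster tibble, `glance()` a one-row
#'   summary, `autoplot()` the standardized profiles by cluster.
#' @export
cluster_profiles <- function(x, k = 5L, n_init = 25L, seed = 1L,
                             features = NULL) {
  v <- norm_values(x)
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (nrow(v) < k) abort("need at least `k` feature profiles.")
  rsd <- apply(v, 1, sd)
  if (any(rsd == 0)) {
    abort(sprintf("zero-variance profile(s): %s",
                  paste(head(rownames(v)[rsd == 0], 5), collapse = ", ")))
  }
  z <- t(scale(t(v)))
  if (k == nrow(v)) {
    # degenerate partition: every profile its own cluster
    return(structure(
      list(k = k, assignment = setNames(seq_len(nrow(z)), rownames(z)),
           centroids = z, inertia = 0, sizes = rep(1L, k), z = z,
           seed = seed, n_init = n_init),
      class = "coexpr_clusters"
    ))
  }
  km <- withr::with_seed(derive_seed(seed, "kmeans"), {
    kmeans(z, centers = k, nstart = n_init, iter.max = 100L)
  })
  structure(
    list(k = k, assignment = setNames(km$cluster, rownames(z)),
         centroids = km$centers, inertia = km$tot.withinss,
         sizes = km$size, z = z, seed = seed, n_init = n_init),
    class = "coexpr_clusters"
  )
}

#' @export
print.coexpr_clusters <- function(x, ...) {
  cat(sprintf("<coexpr_clusters> k = %d, sizes: %s, inertia = %.3f\n",
              x$k, paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' @rdname cluster_profiles
#' @param ... Unused.
#' @method tidy coexpr_clusters
#' @export
tidy.coexpr_clusters <- function(x, ...) {
  tibble(feature = names(x$assignment), cluster = unname(x$assignment))
}

#' @rdname cluster_profiles
#' @method glance coexpr_clusters
#' @export
glance.coexpr_clusters <- function(x, ...) {
  tibble(k = x$k, n_features = length(x$assignment), inertia = x$inertia,
         min_size = min(x$sizes), max_size = max(x$sizes))
}

#' @rdname cluster_profiles
#' @param object A `coexpr_clusters`.
#' @method autoplot coexpr_clusters
#' @export
autoplot.coexpr_clusters <- function(object, ...) {
  df <- as_tibble(object$z, rownames = "feature")
  df <- tidyr::pivot_longer(df, -"feature", names_to = "sample",
                            values_to = "z")
  df$sample <- factor(df$sample, levels = colnames(object$z))
  df$cluster <- paste0("cluster ", object$assignment[df$feature])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$z,
                                   group = .data$feature)) +
    ggplot2::geom_line(alpha = 0.15) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "standardized expression")
}

#' Select clusters containing marker features
#'
#' Ranks clusters by how many marker features (e.g. known starch
#' biosynthetic genes) they contain and returns those holding at least
#' `min_fraction` of the markers (any marker, by default).
#'
#' @param clusters A [cluster_profiles()] result.
#' @param markers Non-empty character vector of marker features.
#' @param min_fraction Minimum fraction of all markers a cluster must hold
#'   (default 0 = any marker present).
#'
#' @return Tibble ranked by marker count: `cluster`, `n_markers`,
#'   `n_features`. Zero rows (with a warning) when no marker was clustered.
#' @export
select_clusters <- function(clusters, markers, min_fraction = 0) {
  stopifnot(inherits(clusters, "coexpr_clusters"))
  if (length(markers) == 0) abort("`markers` must be non-empty.")
  hits <- clusters$assignment[names(clusters$assignment) %in% markers]
  if (length(hits) == 0) {
    warn("no marker feature present in any cluster; empty selection.")
    return(tibble(cluster = integer(), n_markers = integer(),
                  n_features = integer()))
  }
  counts <- table(factor(hits, levels = seq_len(clusters$k)))
  out <- tibble(
    cluster = as.integer(names(counts)),
    n_markers = as.integer(counts),
    n_features = as.integer(tabulate(clusters$assignment, clusters$k))
  )
  out <- out[out$n_markers > 0 & out$n_markers >= min_fraction * length(markers), ]
  dplyr::arrange(out, dplyr::desc(.data$n_markers))
}

#' Functional composition of a feature set
#'
#' Category counts and percentages over a feature set, using a controlled
#' annotation vocabulary ("metabolism", "storage protein",
#' "transcription factor", "unknown", ...). Features missing from the
#' annotation count as "unknown".
#'
#' @param features Non-empty character vector.
#' @param annotation Tibble with columns `feature`, `category`.
#'
#' @return Tibble: `category`, `count`, `percent` (sums to 100 up to
#'   rounding), ordered by count.
#' @export
summarize_function <- function(features, annotation) {
  if (length(features) == 0) abort("`features` is empty.")
  cat_of <- setNames(annotation$category, annotation$feature)
  categories <- unname(cat_of[features])
  categories[is.na(categories)] <- "unknown"
  counts <- sort(table(categories), decreasing = TRUE)
  tibble(
    category = names(counts),
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / length(features)
  )
}

#' Extract transcription-factor candidates from selected clusters
#'
#' Features annotated as transcription factors inside the marker-bearing
#' clusters, ranked by the Pearson correlation of their standardized
#' profile with the mean profile of the marker features (descending) — the
#' co-expression argument that a regulator should track its putative
#' targets.
#'
#' @param clusters A [cluster_profiles()] result.
#' @param annotation Tibble with columns `feature`, `category`.
#' @param markers Marker feature set used to pick clusters and to build the
#'   reference profile.
#' @param selected Optional integer cluster ids; defaults to
#'   [select_clusters()] on `markers`.
#' @param category Annotation label identifying candidates (default
#'   "transcription factor").
#' @param min_fraction Passed to [select_clusters()].
#'
#' @return Tibble ordered by `correlation_to_markers` (descending):
#'   `feature`, `cluster`, `correlation_to_markers`. Possibly empty.
#' @export
extract_tf_candidates <- function(clusters, annotation, markers,
                                  selected = NULL,
                                  category = "transcription factor",
                                  min_fraction = 0) {
  stopifnot(inherits(clusters, "coexpr_clusters"))
  if (is.null(selected)) {
    selected <- if (length(markers) == 0) integer(0) else
      suppressWarnings(select_clusters(clusters, markers, min_fraction))$cluster
  }
  in_sel <- names(clusters$assignment)[clusters$assignment %in% selected]
  cat_of <- setNames(annotation$category, annotation$feature)
  tfs <- in_sel[!is.na(cat_of[in_sel]) & cat_of[in_sel] == category]
  if (length(tfs) == 0) {
    return(tibble(feature = character(), cluster = integer(),
                  correlation_to_markers = double()))
  }
  mk <- intersect(markers, rownames(clusters$z))
  ref <- if (length(mk)) colMeans(clusters$z[mk, , drop = FALSE]) else
    colMeans(clusters$z[in_sel, , drop = FALSE])
  corr <- apply(clusters$z[tfs, , drop = FALSE], 1, cor, y = ref)
  out <- tibble(
    feature = tfs,
    cluster = unname(clusters$assignment[tfs]),
    correlation_to_markers = unname(corr)
  )
  dplyr::arrange(out, dplyr::desc(.data$correlation_to_markers))
}
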