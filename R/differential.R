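#' Volcano-plot differential selection between two conditions
#'
#' Per feature, the orientation-free fold change
#' `max(mean_A/mean_B, mean_B/mean_A)` of normalized intensities and a
#' two-sided t-test on log2 values. Multiple-testing correction
#' (Benjamini-Hochberg) is gated on the experiment's replication: it is
#' applied when both contrasted conditions have at least
#' `correct_min_replicates` (default 4) replicates, and omitted for
#' two-replicate designs — encoding the analysis convention the package
#' reproduces. A feature passes when its fold change reaches `fc_cutoff`
#' and its (adjusted, where applicable) p-value is at most `alpha`.
#'
#' @param norm A [normalize_expression()] result or numeric matrix.
#' @param design Tibble with columns `sample`, `experiment`, `condition`,
#'   `replicate`.
#' @param experiment Experiment id to contrast within.
#' @param pair Character length-2: the two condition labels, or `NULL` to
#'   contrast the extreme pair (conditions with the largest and smallest
#'   mean over all features).
#' @param fc_cutoff Fold-change cutoff (>= 1, inclusive; default 2).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`);
#'   `FALSE` gives Welch's test. With two replicates per condition the
#'   Welch-Satterthwaite df collapses toward 1 and the test has little
#'   power, hence the pooled default.
#' @param correct `"auto"` (replicate-gated, default), `"bh"` or `"none"`.
#' @param correct_min_replicates Replicate count at which `"auto"` applies
#'   BH (default 4).
#'
#' @return A `de_result` tibble: `feature`, `mean_a`, `mean_b`, `log2_fc`
#'   (signed, b over a), `fold_change` (orientation-free, >= 1), `p_value`,
#'   `adjusted_p` (NA when uncorrected), `passes`. Attributes record the
#'   experiment, pair, replicate counts and whether BH was applied.
#' @export
select_differential <- function(norm, design, experiment, pair = NULL,
                                fc_cutoff = 2, alpha = 0.05,
                                var_equal = TRUE,
                                correct = c("auto", "bh", "none"),
                                correct_min_replicates = 4L) {
  correct <- match.arg(correct)
  if (fc_cutoff < 1) abort("`fc_cutoff` must be >= 1.")
  v <- norm_values(norm)
  des <- design[design$experiment == experiment, , drop = FALSE]
  if (nrow(des) == 0) abort(sprintf("experiment '%s' not found in design.", experiment))
  if (is.null(pair)) pair <- extreme_pair(v, des)
  if (length(pair) != 2L || !all(pair %in% des$condition)) {
    abort("`pair` must name two conditions present in the experiment.")
  }
  cols_a <- des$sample[des$condition == pair[1]]
  cols_b <- des$sample[des$condition == pair[2]]
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    abort("both conditions need at least 2 replicates.")
  }
  a <- v[, cols_a, drop = FALSE]
  b <- v[, cols_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  if (any(mean_a == 0) || any(mean_b == 0)) {
    abort("zero condition means; fold change is undefined.")
  }
  fc <- pmax(mean_a / mean_b, mean_b / mean_a)
  p <- row_t_test(log2(a), log2(b), var_equal = var_equal)
  apply_bh <- switch(correct,
    auto = min(length(cols_a), length(cols_b)) >= correct_min_replicates,
    bh = TRUE,
    none = FALSE
  )
  adj <- if (apply_bh) p.adjust(p, method = "BH") else rep(NA_real_, length(p))
  p_eff <- if (apply_bh) adj else p
  out <- tibble(
    feature = rownames(v) %||% as.character(seq_len(nrow(v))),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2_fc = unname(log2(mean_b / mean_a)),
    fold_change = unname(fc), p_value = unname(p), adjusted_p = unname(adj),
    passes = unname(fc >= fc_cutoff & p_eff <= alpha)
  )
  structure(out, class = c("de_result", class(out)),
            experiment = experiment, pair = pair,
            n_replicates = c(length(cols_a), length(cols_b)),
            corrected = apply_bh, fc_cutoff = fc_cutoff, alpha = alpha,
            var_equal = var_equal)
}

# conditions with the largest and smallest overall mean expression
extreme_pair <- function(v, des) {
  cond_means <- vapply(split(des$sample, des$condition), function(s) {
    mean(v[, s, drop = FALSE])
  }, numeric(1))
  c(names(which.min(cond_means)), names(which.max(cond_means)))
}

# vectorized two-sample t-test on rows; pooled or Welch
row_t_test <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * pt(-abs(t), df)
  # identical rows: zero difference and zero variance -> no evidence
  p[se == 0 & ma == mb] <- 1
  p
}

#' Volcano plot of a differential result
#'
#' @param object A `de_result` from [select_differential()].
#' @param ... Unused.
#' @return A ggplot: signed log2 fold change vs -log10 p, passing features
#'   highlighted, cutoffs drawn.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  fc_cutoff <- attr(object, "fc_cutoff")
  alpha <- attr(object, "alpha")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_cutoff), log2(fc_cutoff)),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(log[2] ~ fold ~ change),
      y = expression(-log[10] ~ p),
      colour = "selected",
      subtitle = sprintf("%s: %s vs %s (%s)", attr(object, "experiment"),
                         attr(object, "pair")[1], attr(object, "pair")[2],
                         if (attr(object, "corrected")) "BH-corrected" else "uncorrected")
    )
}

#' Intersect differentially expressed feature sets across experiments
#'
#' Venn-style combination of per-experiment selections: features
#' differentially expressed under every condition survive, and all Venn
#' region cardinalities are reported.
#'
#' @param sets Named list (>= 2) of character feature vectors, or of
#'   `de_result` objects (their passing features are used).
#'
#' @return A `venn_result`: list with `common` (character vector),
#'   `regions` (tibble: one row per non-empty membership pattern, columns
#'   per set plus `count`), and `sets`.
#' @export
intersect_feature_sets <- function(sets) {
  if (length(sets) < 2L) abort("need at least 2 sets.")
  sets <- lapply(sets, function(s) {
    if (inherits(s, "de_result")) s$feature[s$passes] else as.character(s)
  })
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, paste, collapse = "")
  counts <- table(pattern)
  regions <- purrr::map_dfr(names(counts), function(p) {
    bits <- as.logical(as.integer(strsplit(gsub("TRUE", "1", gsub("FALSE", "0", p)),
                                           "")[[1]]))
    out <- as.list(bits)
    names(out) <- names(sets)
    out$count <- as.integer(counts[[p]])
    as_tibble(out)
  })
  common <- universe[rowSums(member) == length(sets)]
  structure(list(common = common, regions = regions, sets = sets),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> %d sets, %d features in common\n",
              length(x$sets), length(x$common)))
  print(x$regions)
  invisible(x)
}
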