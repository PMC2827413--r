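#' Aggregate technical qPCR replicates
#'
#' Mean and standard deviation of Ct cycles per gene, role and group.
#'
#' @param ct_data Tibble with columns `gene`, `role` (`"target"` or
#'   `"reference"`), `group` (`"control"` or `"sample"`), `replicate`, `ct`
#'   and `efficiency`.
#'
#' @return Tibble: `gene`, `role`, `group`, `efficiency`, `n`, `ct_mean`,
#'   `ct_sd`.
#' @export
aggregate_technical <- function(ct_data) {
  need <- c("gene", "role", "group", "ct", "efficiency")
  if (!all(need %in% names(ct_data))) {
    abort(sprintf("`ct_data` needs columns %s.", paste(need, collapse = ", ")))
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(ct_data), .data$gene, .data$role, .data$group,
                    .data$efficiency),
    n = dplyr::n(),
    ct_mean = mean(.data$ct),
    ct_sd = if (dplyr::n() > 1) sd(.data$ct) else 0,
    .groups = "drop"
  )
}

#' Pfaffl-method relative expression
#'
#' Efficiency-corrected relative quantification:
#' `ratio = E_t^(dCt_t) / E_r^(dCt_r)` with `dCt = Ct(control) -
#' Ct(sample)` per gene, so induced targets give ratios above 1. Technical
#' replicates are first aggregated to mean Ct. Each target gene is
#' normalized against the reference gene (e.g. ubiquitin `ubi3`) measured
#' in the same groups. With both efficiencies equal to 2 the formula
#' reduces to the familiar `2^(-ddCt)`.
#'
#' Two error estimates accompany each ratio: `ratio_sd_delta`, the
#' first-order propagation of the technical-replicate Ct standard
#' deviations through the ratio, and the `dct_*_sd` components themselves,
#' since conventions differ on which to report.
#'
#' @param ct_data Long tibble as in [aggregate_technical()]. Exactly one
#'   gene must carry `role = "reference"`.
#'
#' @return Tibble, one row per target gene: `gene`, `efficiency_target`,
#'   `efficiency_reference`, `dct_target`, `dct_reference`, `ratio`,
#'   `dct_target_sd`, `dct_reference_sd`, `ratio_sd_delta`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   gene = rep(c("GBSS", "ubi3"), each = 2),
#'   role = rep(c("target", "reference"), each = 2),
#'   group = rep(c("control", "sample"), 2),
#'   replicate = 1, ct = c(25, 22, 20, 19), efficiency = 2
#' )
#' pfaffl_ratio(ct)$ratio  # 2^3 / 2^1 = 4
pfaffl_ratio <- function(ct_data) {
  agg <- aggregate_technical(ct_data)
  if (any(agg$ct_mean <= 0)) abort("Ct values must be positive.")
  if (any(agg$efficiency <= 1 | agg$efficiency > 2)) {
    abort("amplification efficiencies must lie in (1, 2].")
  }
  ref <- agg[agg$role == "reference", ]
  if (length(unique(ref$gene)) != 1L) {
    abort("exactly one reference gene is required.")
  }
  if (!all(c("control", "sample") %in% ref$group)) {
    abort("reference gene needs both control and sample Ct values.")
  }
  rc <- ref[ref$group == "control", ]
  rs <- ref[ref$group == "sample", ]
  dct_ref <- rc$ct_mean - rs$ct_mean
  dct_ref_sd <- sqrt(rc$ct_sd^2 / rc$n + rs$ct_sd^2 / rs$n)
  e_ref <- rc$efficiency

  targets <- agg[agg$role == "target", ]
  purrr::map_dfr(split(targets, targets$gene), function(tg) {
    if (!all(c("control", "sample") %in% tg$group)) {
      abort(sprintf("target '%s' needs both control and sample Ct values.",
                    tg$gene[1]))
    }
    tc <- tg[tg$group == "control", ]
    ts <- tg[tg$group == "sample", ]
    dct_t <- tc$ct_mean - ts$ct_mean
    dct_t_sd <- sqrt(tc$ct_sd^2 / tc$n + ts$ct_sd^2 / ts$n)
    e_t <- tc$efficiency
    ratio <- e_t^dct_t / e_ref^dct_ref
    # delta-method sd of the ratio from Ct-level technical variation
    log_var <- (log(e_t) * dct_t_sd)^2 + (log(e_ref) * dct_ref_sd)^2
    tibble(
      gene = tg$gene[1],
      efficiency_target = e_t, efficiency_reference = e_ref,
      dct_target = dct_t, dct_reference = dct_ref,
      ratio = ratio,
      dct_target_sd = dct_t_sd, dct_reference_sd = dct_ref_sd,
      ratio_sd_delta = ratio * sqrt(log_var)
    )
  })
}

#' Generate a synthetic qPCR Ct table with known ratios
#'
#' Inverts the Pfaffl relation: given true expression ratios, target and
#' reference efficiencies and a reference delta-Ct, control/sample Ct
#' values are constructed so that [pfaffl_ratio()] recovers the truth
#' exactly at zero jitter; technical-replicate jitter is then added.
#'
#' @param true_ratios Named numeric vector of true fold changes (> 0), one
#'   per target gene.
#' @param efficiency_target,efficiency_reference Fold amplification per
#'   cycle, in (1, 2].
#' @param dct_reference True reference-gene `Ct(control) - Ct(sample)`
#'   (default 0: stable reference).
#' @param n_technical Technical replicates per well (default 3).
#' @param jitter_sd Ct jitter sd in cycles (default 0).
#' @param ct_reference_control,ct_target_control Baseline control Ct values.
#' @param reference_gene Reference gene name (default `"ubi3"`).
#' @param seed Integer seed.
#'
#' @return List: `ct` (long tibble as taken by [pfaffl_ratio()]) and
#'   `truth` (tibble: `gene`, `true_ratio`).
#' @export
generate_qpcr <- function(true_ratios, efficiency_target = 2,
                          efficiency_reference = 2, dct_reference = 0,
                          n_technical = 3L, jitter_sd = 0,
                          ct_reference_control = 20,
                          ct_target_control = 25,
                          reference_gene = "ubi3", seed = 1L) {
  if (is.null(names(true_ratios)) || any(names(true_ratios) == "")) {
    abort("`true_ratios` must be a named vector (one name per target gene).")
  }
  if (any(true_ratios <= 0)) abort("`true_ratios` must be > 0.")
  if (any(c(efficiency_target, efficiency_reference) <= 1) ||
      any(c(efficiency_target, efficiency_reference) > 2)) {
    abort("efficiencies must lie in (1, 2].")
  }
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  eff_t <- rep_len(efficiency_target, length(true_ratios))
  # dCt_t solving ratio = E_t^dct_t / E_r^dct_ref
  dct_t <- (log(true_ratios) + dct_reference * log(efficiency_reference)) /
    log(eff_t)
  rows <- list(tibble(
    gene = reference_gene, role = "reference",
    group = rep(c("control", "sample"), each = n_technical),
    ct = rep(c(ct_reference_control, ct_reference_control - dct_reference),
             each = n_technical),
    efficiency = efficiency_reference
  ))
  for (i in seq_along(true_ratios)) {
    rows[[i + 1]] <- tibble(
      gene = names(true_ratios)[i], role = "target",
      group = rep(c("control", "sample"), each = n_technical),
      ct = rep(c(ct_target_control, ct_target_control - dct_t[i]),
               each = n_technical),
      efficiency = eff_t[i]
    )
  }
  ct <- dplyr::bind_rows(rows)
  ct$replicate <- rep(seq_len(n_technical), nrow(ct) / n_technical)
  withr::with_seed(derive_seed(seed, "qpcr-jitter"), {
    if (jitter_sd > 0) ct$ct <- ct$ct + rnorm(nrow(ct), sd = jitter_sd)
  })
  list(
    ct = ct[, c("gene", "role", "group", "replicate", "ct", "efficiency")],
    truth = tibble(gene = names(true_ratios), true_ratio = unname(true_ratios))
  )
}
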