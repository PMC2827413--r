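#' Estimate tuber growth velocity from repeated volume measurements
#'
#' Fits, per tuber, volume (cm^3) against time (days) and reports the slope
#' as growth velocity in cm^3/day, together with the fit's r-squared and a
#' growing / non-growing call (see [classify_growth()]). The default is an
#' ordinary least-squares fit over all scans; `method = "endpoint"` uses the
#' first/last difference quotient instead. For exactly two observations both
#' methods coincide and r-squared is 1.
#'
#' @param data Data frame with columns `tuber_id`, `time_days`, `volume_cm3`
#'   (additional columns are ignored). Each tuber needs >= 2 observations at
#'   strictly increasing times.
#' @param method `"ols"` (default) or `"endpoint"`.
#' @param abs_threshold,rel_threshold Growth-call thresholds passed to
#'   [classify_growth()] (cm^3/day and fraction/day).
#'
#' @return A `growth_fit` object; its `estimates` tibble has one row per
#'   tuber: `tuber_id`, `velocity_cm3_per_day`, `intercept_cm3`, `r_squared`,
#'   `mean_volume_cm3`, `n_obs`, `growing`. `tidy()` returns that tibble,
#'   `glance()` a one-row summary, `autoplot()` the fitted series.
#' @export
#' @examples
#' d <- tibble::tibble(tuber_id = "t1", time_days = 0:2,
#'                     volume_cm3 = c(10, 12, 14))
#' tidy(estimate_velocity(d))
estimate_velocity <- function(data, method = c("ols", "endpoint"),
                              abs_threshold = 0.1, rel_threshold = 0.01) {
  method <- match.arg(method)
  need <- c("tuber_id", "time_days", "volume_cm3")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  groups <- split(as_tibble(data)[need], data$tuber_id)
  est <- purrr::map(groups, function(g) {
    g <- dplyr::arrange(g, .data$time_days)
    if (nrow(g) < 2L) abort(sprintf("tuber %s has < 2 observations.", g$tuber_id[1]))
    if (anyDuplicated(g$time_days)) {
      abort(sprintf("tuber %s has duplicate scan times.", g$tuber_id[1]))
    }
    if (method == "ols") {
      fit <- lm(volume_cm3 ~ time_days, data = g)
      slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
      sst <- sum((g$volume_cm3 - mean(g$volume_cm3))^2)
      ssr <- sum(fit$residuals^2)
      r2 <- if (sst <= .Machine$double.eps * max(1, mean(g$volume_cm3)^2)) 1
            else 1 - ssr / sst
    } else {
      n <- nrow(g)
      slope <- (g$volume_cm3[n] - g$volume_cm3[1]) / (g$time_days[n] - g$time_days[1])
      icpt <- g$volume_cm3[1] - slope * g$time_days[1]
      pred <- icpt + slope * g$time_days
      sst <- sum((g$volume_cm3 - mean(g$volume_cm3))^2)
      r2 <- if (sst == 0) 1 else max(0, 1 - sum((g$volume_cm3 - pred)^2) / sst)
    }
    mv <- mean(g$volume_cm3)
    tibble(
      tuber_id = g$tuber_id[1], velocity_cm3_per_day = slope,
      intercept_cm3 = icpt, r_squared = min(max(r2, 0), 1),
      mean_volume_cm3 = mv, n_obs = nrow(g),
      growing = classify_growth(slope, mv, abs_threshold, rel_threshold)
    )
  })
  structure(
    list(estimates = dplyr::bind_rows(est), data = as_tibble(data)[need],
         method = method, abs_threshold = abs_threshold,
         rel_threshold = rel_threshold),
    class = "growth_fit"
  )
}

#' Classify a tuber as growing or non-growing
#'
#' The original campaign separates growing tubers from those that have
#' virtually stopped growing without stating a numeric rule; this dual rule
#' calls a tuber growing when its velocity exceeds an absolute floor or a
#' fraction of its own mean volume per day.
#'
#' @param velocity Growth velocity, cm^3/day.
#' @param mean_volume Mean tuber volume over the series, cm^3 (>= 0).
#' @param abs_threshold Absolute velocity threshold, cm^3/day (default 0.1).
#' @param rel_threshold Relative threshold, fraction of mean volume per day
#'   (default 0.01).
#'
#' @return Logical: `velocity > abs_threshold | velocity > rel_threshold *
#'   mean_volume`.
#' @export
classify_growth <- function(velocity, mean_volume, abs_threshold = 0.1,
                            rel_threshold = 0.01) {
  if (abs_threshold < 0 || rel_threshold < 0) abort("thresholds must be >= 0.")
  if (any(mean_volume < 0)) abort("`mean_volume` must be >= 0.")
  velocity > abs_threshold | velocity > rel_threshold * mean_volume
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %d tubers, method = %s\n",
              nrow(x$estimates), x$method))
  print(x$estimates)
  invisible(x)
}

#' @rdname estimate_velocity
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) x$estimates

#' @rdname estimate_velocity
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  e <- x$estimates
  tibble(
    n_tubers = nrow(e), n_growing = sum(e$growing),
    median_velocity_cm3_per_day = median(e$velocity_cm3_per_day),
    min_r_squared = min(e$r_squared), method = x$method
  )
}

#' @rdname estimate_velocity
#' @param object A `growth_fit`.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$time_days, .data$volume_cm3,
                               colour = .data$tuber_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "time (days)", y = expression(volume ~ (cm^3)),
                  colour = "tuber")
}
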