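# ROI descriptive statistics and test-retest repeatability metrics
# (CV, RMSCV, ICC) over ROI-mean parameter values.

.map_metrics <- c("T_mono", "T_short", "T_long", "F_short", "F_long")

#' Per-ROI mean parameter values of one map set
#'
#' Averages each parameter map over the voxels of every ROI and reports the
#' share of voxels with a valid (retained) biexponential fit.
#'
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param labels 3D integer/character array of ROI labels aligned with the
#'   maps; 0, 1, `NA` or `"background"` marks background (a phantom's
#'   `label_map` works directly).
#' @return A tibble with one row per ROI x metric: `roi`, `metric`, `value`
#'   (map metrics in ms or percent, plus `ratio` = percent of ROI voxels
#'   with a valid biexponential fit) and `n_voxels`.
#' @export
roi_means <- function(maps, labels) {
  stopifnot(inherits(maps, "parameter_maps"))
  lab <- as.vector(labels)
  if (is.numeric(lab)) {
    lab <- ifelse(lab <= 1L, NA_character_, .roi_levels[lab])
  }
  lab[lab == "background"] <- NA_character_
  if (length(lab) != prod(maps$grid_shape)) {
    stop("`labels` must be aligned with the maps", call. = FALSE)
  }
  df <- tibble::tibble(
    roi = lab,
    T_mono = as.vector(maps$T_mono), T_short = as.vector(maps$T_short),
    T_long = as.vector(maps$T_long), F_short = as.vector(maps$F_short),
    F_long = as.vector(maps$F_long)) |>
    dplyr::filter(!is.na(.data$roi))
  if (nrow(df) == 0L) stop("no labelled voxels", call. = FALSE)
  empty <- setdiff(unique(lab[!is.na(lab)]), unique(df$roi))
  if (length(empty)) warning("empty ROI(s): ", paste(empty, collapse = ", "))
  df |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      ratio = 100 * mean(!is.na(.data$T_short)),  # before across() remaps cols
      dplyr::across(dplyr::all_of(.map_metrics),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop") |>
    tidyr::pivot_longer(cols = c(dplyr::all_of(.map_metrics), "ratio"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) |>
    dplyr::select("roi", "metric", "value", "n_voxels")
}

#' ROI summary across subjects
#'
#' Computes per-subject ROI means first, then the mean and SD of each
#' metric across subjects — the layout of a per-muscle relaxation summary
#' table (`T_mono`, `T_short`, `F_short`, `T_long`, `F_long` and the percent
#' of voxels with a valid biexponential fit).
#'
#' @param maps_list A `parameter_maps` object or a list of them (one per
#'   subject).
#' @param labels ROI label volume shared by all subjects (see [roi_means()]).
#' @return A tibble per ROI x metric: `roi`, `metric`, `mean`, `sd`
#'   (`NA` SD for a single subject), `n_subjects`.
#' @export
roi_summary <- function(maps_list, labels) {
  if (inherits(maps_list, "parameter_maps")) maps_list <- list(maps_list)
  stopifnot(length(maps_list) >= 1L)
  purrr::imap_dfr(maps_list, function(m, i) {
    dplyr::mutate(roi_means(m, labels), subject = i)
  }) |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value[!is.na(.data$value)]),
      n_subjects = sum(!is.na(.data$value)), .groups = "drop") |>
    dplyr::mutate(mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean))
}

#' Scan-rescan coefficient of variation
#'
#' \eqn{CV = \sigma / \mu} where \eqn{\mu} and \eqn{\sigma} are the mean and
#' standard deviation of a metric estimated from two scans of the same
#' subject. The sample (n-1) SD convention is used, so for two values
#' \eqn{\sigma = |x_1 - x_2| / \sqrt{2}}; note some authors use the
#' population SD, which differs by a factor \eqn{\sqrt{2}}.
#'
#' @param scan1,scan2 Metric value from each scan (vectorised).
#' @return CV as a dimensionless fraction.
#' @examples
#' cv_scan_rescan(20, 30)  # 0.2828...
#' @export
cv_scan_rescan <- function(scan1, scan2) {
  mu <- (scan1 + scan2) / 2
  if (any(mu == 0)) stop("CV undefined: mean of the two scans is 0",
                         call. = FALSE)
  sigma <- abs(scan1 - scan2) / sqrt(2)
  sigma / mu
}

#' Root-mean-square CV across subjects
#'
#' Pools per-subject scan-rescan spread into a single repeatability figure:
#' \deqn{RMSCV = \sqrt{\textstyle\frac{1}{n}\sum_i \sigma_i^2} \Big/
#'   \textstyle\frac{1}{n}\sum_i \mu_i,}
#' with \eqn{(\mu_i, \sigma_i)} the per-subject mean and SD across sessions.
#'
#' @param mu Per-subject means (length >= 2; the study used 3 subjects).
#' @param sigma Per-subject SDs across sessions (same length).
#' @return RMSCV as a dimensionless fraction.
#' @examples
#' rmscv(mu = c(10, 10, 10), sigma = c(3, 4, 0))  # 0.28868
#' @export
rmscv <- function(mu, sigma) {
  stopifnot(length(mu) == length(sigma), length(mu) >= 2L)
  denom <- mean(mu)
  if (denom == 0) stop("RMSCV undefined: mean of subject means is 0",
                       call. = FALSE)
  sqrt(mean(sigma^2)) / denom
}

#' Intraclass correlation coefficient
#'
#' One-way random-effects ICC,
#' \eqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}, with the variance
#' components estimated from the one-way ANOVA mean squares over a
#' subject-by-session matrix: \eqn{\sigma_w^2 = MSW} and
#' \eqn{\sigma_b^2 = (MSB - MSW)/k} for `k` sessions, negative estimates
#' truncated to zero.
#'
#' @param values Numeric matrix, subjects in rows, sessions in columns
#'   (>= 2 each).
#' @return A list with `icc` (in `[0, 1]`; `NA` with a warning for a
#'   constant matrix), `sigma_b2`, `sigma_w2`.
#' @examples
#' icc(matrix(c(10, 20, 30, 12, 22, 32), ncol = 2))
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  subj_means <- rowMeans(values)
  msb <- k * stats::var(subj_means)
  msw <- sum((values - subj_means)^2) / (n * (k - 1))
  sigma_w2 <- msw
  sigma_b2 <- max((msb - msw) / k, 0)
  if (sigma_b2 + sigma_w2 == 0) {
    warning("constant matrix: ICC undefined")
    return(list(icc = NA_real_, sigma_b2 = 0, sigma_w2 = 0))
  }
  list(icc = sigma_b2 / (sigma_b2 + sigma_w2),
       sigma_b2 = sigma_b2, sigma_w2 = sigma_w2)
}

#' Test-retest repeatability table
#'
#' Computes, for every ROI x metric, the per-subject scan-rescan CVs, the
#' pooled RMSCV and the one-way random-effects ICC from a tidy table of
#' ROI-mean values.
#'
#' @param data Data frame with columns `subject`, `session`, `roi`,
#'   `metric`, `value` (one row per combination; >= 2 subjects and >= 2
#'   sessions per ROI x metric).
#' @return An object of class `repeatability_result`: a tibble per ROI x
#'   metric with `rmscv_pct` (percent), `icc`, `sigma_b2`, `sigma_w2`,
#'   `n_subjects`, `n_sessions`.
#' @examples
#' d <- tidyr::expand_grid(subject = 1:3, session = 1:2,
#'                         roi = "GM", metric = "T_mono")
#' d$value <- 28 + d$subject + 0.3 * d$session
#' repeatability_metrics(d)
#' @export
repeatability_metrics <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject", "session", "roi", "metric", "value") %in%
                  names(data)))
  out <- data |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      wide <- d |>
        dplyr::select("subject", "session", "value") |>
        tidyr::pivot_wider(names_from = "session", values_from = "value") |>
        dplyr::arrange(.data$subject)
      m <- as.matrix(wide[, -1, drop = FALSE])
      if (nrow(m) < 2L || ncol(m) < 2L || any(!is.finite(m))) {
        return(tibble::tibble(rmscv_pct = NA_real_, icc = NA_real_,
                              sigma_b2 = NA_real_, sigma_w2 = NA_real_,
                              n_subjects = nrow(m), n_sessions = ncol(m)))
      }
      ic <- icc(m)
      tibble::tibble(
        rmscv_pct = 100 * rmscv(rowMeans(m), apply(m, 1, stats::sd)),
        icc = ic$icc, sigma_b2 = ic$sigma_b2, sigma_w2 = ic$sigma_w2,
        n_subjects = nrow(m), n_sessions = ncol(m))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("repeatability_result", class(out)))
}

#' Plot repeatability metrics per ROI
#'
#' ICC and RMSCV bars per ROI, facetted by metric.
#'
#' @param object A `repeatability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repeatability_result <- function(object, ...) {
  long <- object |>
    dplyr::select("roi", "metric", "rmscv_pct", "icc") |>
    dplyr::mutate(icc = 100 * .data$icc) |>
    tidyr::pivot_longer(c("rmscv_pct", "icc"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::mutate(statistic = dplyr::recode(.data$statistic,
                                            rmscv_pct = "RMSCV (%)",
                                            icc = "ICC (%)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$roi, .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
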