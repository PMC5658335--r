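# Voxel-wise mono/biexponential fitting.
#
# The biexponential fit is parameterised by the component amplitudes
# (A_s, A_l) and time constants (T_s, T_l); S0 = A_s + A_l. This removes the
# S0 * a_i scale redundancy of the textbook form. Bounds bracket the in-vivo
# muscle ranges with margin: T_s in [0.5, 30] ms, T_l in [5, 150] ms.

.bi_bounds <- list(T_s = c(0.5, 30), T_l = c(5, 150))
.mono_T_max <- 2000  # ms; hitting this bound marks the fit degenerate (no decay)

# Amplitudes for fixed (T_s, T_l) solve a 2-column linear least-squares
# problem; used by the coarse-grid start.
.amps_for_T <- function(y, t, T_s, T_l) {
  X <- cbind(exp(-t / T_s), exp(-t / T_l))
  a <- tryCatch(qr.solve(X, y), error = function(e) c(NA_real_, NA_real_))
  pmax(a, 0)
}

.rss <- function(y, yhat) sum((y - yhat)^2)

#' Fit a monoexponential decay to one voxel
#'
#' Least-squares fit of \eqn{S(t) = A e^{-t/T}} to a sampled decay, using a
#' log-linear closed form as the starting point and bounded
#' Levenberg-Marquardt refinement.
#'
#' @param signal Numeric vector of non-negative sample values, one per
#'   schedule time.
#' @param schedule An [acq_schedule()] with matching length.
#' @return A list with `params` ([decay_params()] with the fitted `S0` and
#'   `T_mono`), `rss` (residual sum of squares), `fitted` values and
#'   `status` (`"ok"`, `"degenerate"` when no decay is resolvable, or
#'   `"failed"`).
#' @examples
#' sch <- protocol_schedule("T1rho")
#' y <- mono_signal(sch$times, decay_params(T_mono = 25))
#' fit_mono(y, sch)$params
#' @export
fit_mono <- function(signal, schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  t <- schedule$times
  if (length(signal) != length(t)) {
    stop("`signal` length must match the schedule", call. = FALSE)
  }
  if (length(t) < 2L) stop("need at least 2 samples", call. = FALSE)
  bad <- list(params = NULL, rss = NA_real_, fitted = NULL, status = "failed")
  if (any(!is.finite(signal)) || all(signal == 0) || any(signal < 0)) {
    return(bad)
  }

  # log-linear start on the strictly positive samples
  pos <- signal > 0
  if (sum(pos) >= 2L) {
    co <- stats::coef(stats::lm(log(signal[pos]) ~ t[pos]))
    A0 <- exp(co[[1]])
    T0 <- if (is.finite(co[[2]]) && co[[2]] < 0) -1 / co[[2]] else .mono_T_max
  } else {
    A0 <- max(signal); T0 <- mean(t)
  }
  A0 <- min(max(A0, 1e-6), 2 * max(signal))
  T0 <- min(max(T0, 0.1), .mono_T_max)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A0, T0),
      lower = c(1e-12, 0.1), upper = c(2 * max(signal), .mono_T_max),
      fn = function(p) p[1] * exp(-t / p[2]) - signal,
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- fit$par
  status <- if (p[2] >= 0.995 * .mono_T_max) "degenerate" else "ok"
  fitted <- p[1] * exp(-t / p[2])
  list(params = decay_params(S0 = p[1], T_mono = p[2]),
       rss = .rss(signal, fitted), fitted = fitted, status = status)
}

# Candidate starts for the biexponential optimiser: (i) split of the mono
# estimate, (ii) the in-vivo global means for the modality, (iii) best of a
# coarse (T_s, T_l) grid with linear-least-squares amplitudes.
.bi_starts <- function(signal, t, schedule, mono_fit) {
  S0 <- if (!is.null(mono_fit$params)) mono_fit$params$S0 else max(signal)
  Tm <- if (!is.null(mono_fit$params)) mono_fit$params$T_mono else mean(t)
  starts <- list()
  Ts1 <- min(max(Tm / 3, .bi_bounds$T_s[1]), .bi_bounds$T_s[2])
  Tl1 <- min(max(2 * Tm, .bi_bounds$T_l[1]), .bi_bounds$T_l[2])
  starts[[1]] <- c(0.2 * S0, Ts1, 0.8 * S0, Tl1)
  glob <- if (schedule$modality == "T1rho") c(6.3, 37, 0.25) else c(6.1, 35, 0.20)
  starts[[2]] <- c(glob[3] * S0, glob[1], (1 - glob[3]) * S0, glob[2])
  grid <- expand.grid(T_s = c(1, 2, 4, 8, 15, 25), T_l = c(10, 20, 35, 60, 100, 140))
  grid <- grid[grid$T_l > grid$T_s, ]
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- .amps_for_T(signal, t, grid$T_s[i], grid$T_l[i])
    if (any(!is.finite(a))) next
    yhat <- a[1] * exp(-t / grid$T_s[i]) + a[2] * exp(-t / grid$T_l[i])
    r <- .rss(signal, yhat)
    if (r < best_rss) { best_rss <- r; best <- c(a[1], grid$T_s[i], a[2], grid$T_l[i]) }
  }
  if (!is.null(best)) starts[[3]] <- best
  starts
}

#' Fit a biexponential decay to one voxel
#'
#' Bounded Levenberg-Marquardt fit of
#' \eqn{S(t) = A_s e^{-t/T_s} + A_l e^{-t/T_l}} with multi-start
#' initialisation (mono-estimate split, in-vivo global means, coarse grid);
#' the start with the smallest residual wins. Component order `T_s <= T_l`
#' is enforced on output. `S0 = A_s + A_l`.
#'
#' When `S0` is given, the amplitude sum is fixed to it (the model reduces
#' to \eqn{S_0 (F e^{-t/T_s} + (1-F) e^{-t/T_l})} with 3 free parameters,
#' the convention of the Monte Carlo machinery where the simulated initial
#' signal is known to be 1); by default `S0` is estimated freely (the
#' voxel-mapping convention).
#'
#' @inheritParams fit_mono
#' @param S0 Optional known initial amplitude; `NULL` (default) estimates it.
#' @return A list with `params` (biexponential [decay_params()]),
#'   `fractions` (`F_s`, `F_l` percent), `rss`, `fitted`, `excluded`
#'   (separation rule, see [apply_exclusion()]) and `status`.
#' @examples
#' sch <- protocol_schedule("T1rho")
#' y <- bi_signal(sch$times, decay_params(a_s = 0.2, T_s = 5, a_l = 0.8, T_l = 35))
#' fit_bi(y, sch)$params
#' @export
fit_bi <- function(signal, schedule, S0 = NULL) {
  stopifnot(inherits(schedule, "acq_schedule"))
  t <- schedule$times
  if (length(signal) != length(t)) {
    stop("`signal` length must match the schedule", call. = FALSE)
  }
  if (length(t) < 5L) {
    stop("biexponential fit needs at least 5 samples (4 shape parameters)",
         call. = FALSE)
  }
  bad <- list(params = NULL, fractions = NULL, rss = NA_real_, fitted = NULL,
              excluded = NA, status = "failed")
  if (any(!is.finite(signal)) || all(signal == 0) || any(signal < 0)) {
    return(bad)
  }

  mono_fit <- fit_mono(signal, schedule)
  fixed_S0 <- !is.null(S0)
  if (fixed_S0) stopifnot(is.numeric(S0), length(S0) == 1L, S0 > 0)
  A_max <- 2 * max(signal)
  if (fixed_S0) {
    # 3 free parameters: F_s in [0, 1], T_s, T_l
    lower <- c(0, .bi_bounds$T_s[1], .bi_bounds$T_l[1])
    upper <- c(1, .bi_bounds$T_s[2], .bi_bounds$T_l[2])
    resid_fn <- function(p) {
      S0 * (p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3])) - signal
    }
    to_par <- function(p4) c(p4[1] / max(p4[1] + p4[3], 1e-12), p4[2], p4[4])
  } else {
    lower <- c(0, .bi_bounds$T_s[1], 0, .bi_bounds$T_l[1])
    upper <- c(A_max, .bi_bounds$T_s[2], A_max, .bi_bounds$T_l[2])
    resid_fn <- function(p) {
      p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) - signal
    }
    to_par <- identity
  }
  clamp <- function(p) pmin(pmax(p, lower + 1e-9), upper - 1e-9)

  best <- NULL; best_rss <- Inf
  for (p0 in .bi_starts(signal, t, schedule, mono_fit)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = clamp(to_par(p0)), lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                             maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- sum(fit$fvec^2)
    if (r < best_rss) { best_rss <- r; best <- fit$par }
  }
  if (is.null(best)) return(bad)

  if (fixed_S0) {
    A_s <- S0 * best[1]; T_s <- best[2]; A_l <- S0 * (1 - best[1]); T_l <- best[3]
  } else {
    A_s <- best[1]; T_s <- best[2]; A_l <- best[3]; T_l <- best[4]
  }
  if (T_s > T_l) {  # canonical order
    tmp <- A_s; A_s <- A_l; A_l <- tmp
    tmp <- T_s; T_s <- T_l; T_l <- tmp
  }
  if (A_s + A_l <= 0) return(bad)
  # zero-amplitude or coincident components: keep as a degenerate bi solution
  degen <- (A_s / (A_s + A_l) < 1e-6) || (A_l / (A_s + A_l) < 1e-6) ||
    (T_s / T_l > 0.999)
  if (T_s >= T_l) T_s <- T_l * 0.999  # guard exact tie for decay_params
  params <- decay_params(S0 = A_s + A_l, a_s = A_s / (A_s + A_l),
                         T_s = T_s, a_l = A_l / (A_s + A_l), T_l = T_l)
  fitted <- A_s * exp(-t / T_s) + A_l * exp(-t / T_l)
  list(params = params,
       fractions = fractions_from_amplitudes(A_s, A_l),
       rss = .rss(signal, fitted), fitted = fitted,
       excluded = apply_exclusion(params),
       status = if (degen) "degenerate" else "ok")
}

#' Component-separation exclusion rule
#'
#' A biexponential fit is only considered resolvable when the two components
#' are well separated: the validity condition is `4 * T_s < T_l` (strict).
#' Voxels failing it are excluded from the biexponential maps.
#'
#' @param params A biexponential [decay_params()].
#' @return `TRUE` if the voxel is excluded (insufficient separation),
#'   `FALSE` if retained.
#' @examples
#' apply_exclusion(decay_params(a_s = .25, T_s = 6.3, a_l = .75, T_l = 37)) # FALSE
#' apply_exclusion(decay_params(a_s = .5, T_s = 10, a_l = .5, T_l = 20))   # TRUE
#' @export
apply_exclusion <- function(params) {
  stopifnot(inherits(params, "decay_params"), params$n_components == 2L)
  !(4 * params$T_s < params$T_l)
}

#' Mono-versus-bi model selection
#'
#' Decides whether the biexponential model is a statistically better
#' description of a voxel's decay than the monoexponential one, using the
#' F-test for nested least-squares models (2 extra parameters) plus
#' degeneracy guards: the verdict is `"bi"` only when the F-test rejects at
#' `alpha` and the bi fit is non-degenerate (`F_s` within 1--99 percent and
#' `T_s / T_l <= 0.99`). A failed bi fit or an essentially perfect mono fit
#' yields `"mono"`.
#'
#' @param result A voxel fit result as returned by [fit_voxel()], or any list
#'   with `mono` and `bi` entries from [fit_mono()] / [fit_bi()] and `n` (the
#'   number of samples).
#' @param alpha Significance level of the nested-model F-test (default 0.05).
#' @return A list with `verdict` (`"mono"` or `"bi"`) and `p_value` of the
#'   F-test (`NA` when not computable).
#' @export
select_model <- function(result, alpha = 0.05) {
  mono <- result$mono; bi <- result$bi; n <- result$n
  out_mono <- function(p = NA_real_) list(verdict = "mono", p_value = p)
  if (is.null(bi) || bi$status == "failed" || is.null(bi$params)) {
    return(out_mono())
  }
  if (is.null(mono) || mono$status == "failed") {
    # no mono reference: accept bi if non-degenerate
    return(list(verdict = if (bi$status == "ok") "bi" else "mono",
                p_value = NA_real_))
  }
  df2 <- n - 4
  if (df2 <= 0) return(out_mono())
  scale <- sum(mono$fitted^2) + .Machine$double.eps
  if (mono$rss <= 1e-16 * scale) return(out_mono(1))  # mono already perfect
  fr <- bi$fractions
  degenerate <- bi$status != "ok" || fr$F_s < 1 || fr$F_s > 99 ||
    bi$params$T_s / bi$params$T_l > 0.99
  if (bi$rss <= 1e-16 * scale) {
    # a (near-)exact bi fit of non-mono data: F -> Inf, p -> 0
    p <- 0
  } else {
    F_stat <- ((mono$rss - bi$rss) / 2) / (bi$rss / df2)
    if (!is.finite(F_stat) || F_stat < 0) return(out_mono())
    p <- stats::pf(F_stat, 2, df2, lower.tail = FALSE)
  }
  list(verdict = if (!degenerate && p < alpha) "bi" else "mono", p_value = p)
}

#' Full mono + bi fit of one voxel
#'
#' Runs [fit_mono()] and [fit_bi()], applies [select_model()] and the
#' separation rule, and returns the complete per-voxel result.
#'
#' @inheritParams fit_mono
#' @param alpha Significance level for [select_model()].
#' @return A list of class `voxel_fit` with `mono`, `bi`, `n`, `verdict`,
#'   `p_value`, `excluded` and `status`.
#' @export
fit_voxel <- function(signal, schedule, alpha = 0.05) {
  ord <- order(schedule$times)  # tolerate permuted (time, sample) input
  if (is.unsorted(schedule$times)) {
    schedule <- acq_schedule(schedule$times[ord], schedule$modality,
                             schedule$snr)
    signal <- signal[ord]
  }
  mono <- fit_mono(signal, schedule)
  bi <- if (length(signal) >= 5L) fit_bi(signal, schedule) else
    list(params = NULL, fractions = NULL, rss = NA_real_, fitted = NULL,
         excluded = NA, status = "failed")
  res <- list(mono = mono, bi = bi, n = length(signal),
              times = schedule$times, signal = signal)
  sel <- select_model(res, alpha)
  res$verdict <- sel$verdict
  res$p_value <- sel$p_value
  res$excluded <- bi$excluded
  res$status <- if (mono$status == "failed" && bi$status == "failed")
    "failed" else "ok"
  class(res) <- "voxel_fit"
  res
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("<voxel_fit> verdict = %s (p = %.3g), excluded = %s\n",
              x$verdict, x$p_value,
              if (is.na(x$excluded)) "NA" else x$excluded))
  if (!is.null(x$mono$params)) print(x$mono$params)
  if (!is.null(x$bi$params)) print(x$bi$params)
  invisible(x)
}

#' Tidy per-voxel fit results for a table of decays
#'
#' The data-frame-first fitting interface: takes a long table of sampled
#' decays (one row per voxel x time point) and returns one row per voxel with
#' the mono and biexponential estimates, the model verdict and the exclusion
#' flag. Rows may arrive in any order; pairs are matched on `time`.
#'
#' @param data A data frame with columns `voxel` (any id), `time` (ms) and
#'   `signal`.
#' @param schedule An [acq_schedule()]; its times must match the per-voxel
#'   times in `data`.
#' @param alpha Significance level for model selection.
#' @return A tibble with one row per voxel: `voxel`, `status`, `S0_mono`,
#'   `T_mono`, `rss_mono`, `S0_bi`, `T_short`, `T_long`, `F_short`, `F_long`,
#'   `rss_bi`, `p_value`, `verdict`, `excluded`.
#' @examples
#' sch <- protocol_schedule("T1rho")
#' d <- tibble::tibble(voxel = 1, time = sch$times,
#'                     signal = bi_signal(sch$times,
#'                       decay_params(a_s = .25, T_s = 6.3, a_l = .75, T_l = 37)))
#' fit_voxels(d, sch)
#' @export
fit_voxels <- function(data, schedule, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("voxel", "time", "signal") %in% names(data)))
  data |>
    dplyr::arrange(.data$voxel, .data$time) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::group_modify(function(d, key) {
      if (!isTRUE(all.equal(d$time, schedule$times))) {
        stop("voxel times do not match the schedule", call. = FALSE)
      }
      tidy_voxel_fit(fit_voxel(d$signal, schedule, alpha))
    }) |>
    dplyr::ungroup()
}

# one-row tibble from a voxel_fit
tidy_voxel_fit <- function(fit) {
  mono_ok <- !is.null(fit$mono$params)
  bi_ok <- !is.null(fit$bi$params)
  tibble::tibble(
    status = fit$status,
    S0_mono = if (mono_ok) fit$mono$params$S0 else NA_real_,
    T_mono = if (mono_ok) fit$mono$params$T_mono else NA_real_,
    rss_mono = fit$mono$rss,
    S0_bi = if (bi_ok) fit$bi$params$S0 else NA_real_,
    T_short = if (bi_ok) fit$bi$params$T_s else NA_real_,
    T_long = if (bi_ok) fit$bi$params$T_l else NA_real_,
    F_short = if (bi_ok) fit$bi$fractions$F_s else NA_real_,
    F_long = if (bi_ok) fit$bi$fractions$F_l else NA_real_,
    rss_bi = fit$bi$rss,
    p_value = fit$p_value,
    verdict = fit$verdict,
    excluded = fit$excluded
  )
}

#' Fit every voxel of a 4D relaxometry volume
#'
#' Applies [fit_voxel()] to each voxel inside `tissue_mask` and assembles the
#' 3D parameter maps. Biexponential maps are populated only at voxels where a
#' biexponential decay is detected (model verdict `bi`) and the separation
#' rule retains the voxel; all other positions are `NA`, so ROI averages of
#' the bi maps are taken over detected voxels only. Deterministic: identical
#' input gives identical maps.
#'
#' @param series 4D numeric array `(x, y, z, time)`; the 4th dimension must
#'   match the schedule length.
#' @param schedule An [acq_schedule()].
#' @param tissue_mask 3D logical/0-1 array matching the spatial dimensions;
#'   `NULL` fits every voxel.
#' @param alpha Significance level for model selection.
#' @return A `parameter_maps` object: list of 3D maps `T_mono`, `T_short`,
#'   `T_long`, `F_short`, `F_long`, the binary `exclusion_mask` (1 =
#'   excluded by the separation rule), `bi_detected` (1 = verdict bi and
#'   retained), `tissue_mask`, plus `modality` and `grid_shape`.
#' @export
fit_volume <- function(series, schedule, tissue_mask = NULL, alpha = 0.05) {
  stopifnot(is.array(series), length(dim(series)) == 4L)
  dims <- dim(series)
  if (dims[4] != length(schedule$times)) {
    stop("4th dimension of `series` must match the schedule length",
         call. = FALSE)
  }
  shape <- dims[1:3]
  if (is.null(tissue_mask)) tissue_mask <- array(TRUE, shape)
  if (!identical(dim(tissue_mask), as.integer(shape)) &&
      !identical(dim(tissue_mask), shape)) {
    stop("`tissue_mask` dimensions must match the series grid", call. = FALSE)
  }
  tissue_mask <- array(as.logical(tissue_mask), shape)

  nvox <- prod(shape)
  mat <- matrix(series, nrow = nvox)  # voxels x time
  idx <- which(tissue_mask)

  blank <- function() array(NA_real_, shape)
  maps <- list(T_mono = blank(), T_short = blank(), T_long = blank(),
               F_short = blank(), F_long = blank(),
               exclusion_mask = blank(), bi_detected = blank())
  n_failed <- 0L
  for (i in idx) {
    fit <- fit_voxel(mat[i, ], schedule, alpha)
    if (fit$status == "failed") { n_failed <- n_failed + 1L; next }
    if (!is.null(fit$mono$params) && fit$mono$status != "failed") {
      maps$T_mono[i] <- fit$mono$params$T_mono
    }
    if (!is.null(fit$bi$params) && fit$bi$status != "failed") {
      maps$exclusion_mask[i] <- as.numeric(fit$excluded)
      detected <- fit$verdict == "bi" && !fit$excluded
      maps$bi_detected[i] <- as.numeric(detected)
      if (detected) {  # bi maps only where a bi decay is detected + retained
        maps$T_short[i] <- fit$bi$params$T_s
        maps$T_long[i] <- fit$bi$params$T_l
        maps$F_short[i] <- fit$bi$fractions$F_s
        maps$F_long[i] <- fit$bi$fractions$F_l
      }
    }
  }
  structure(c(maps, list(tissue_mask = tissue_mask, modality = schedule$modality,
                         grid_shape = shape, n_fitted = length(idx),
                         n_failed = n_failed, alpha = alpha)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  det <- mean(x$bi_detected[x$tissue_mask], na.rm = TRUE)
  cat(sprintf(
    "<parameter_maps> %s, grid %s, %d voxels fitted (%d failed), bi detected in %.1f%%\n",
    x$modality, paste(x$grid_shape, collapse = "x"), x$n_fitted, x$n_failed,
    100 * if (is.finite(det)) det else 0))
  invisible(x)
}

#' Convert parameter maps to a tidy voxel table
#'
#' @param x A `parameter_maps` object.
#' @param ... Unused.
#' @return A tibble with one row per tissue voxel: integer coordinates
#'   `x, y, z` (1-based array indices), the linear index `voxel` and the map
#'   values.
#' @export
as_tibble.parameter_maps <- function(x, ...) {
  maps <- x
  idx <- which(maps$tissue_mask, arr.ind = TRUE)
  lin <- which(maps$tissue_mask)
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3], voxel = lin,
    T_mono = maps$T_mono[lin], T_short = maps$T_short[lin],
    T_long = maps$T_long[lin], F_short = maps$F_short[lin],
    F_long = maps$F_long[lin], excluded = maps$exclusion_mask[lin],
    bi_detected = maps$bi_detected[lin])
}

#' Estimate the SNR of a relaxometry series
#'
#' SNR is taken as the mean tissue signal at the shortest time point divided
#' by the standard deviation of background samples (all time points pooled).
#'
#' @param series 4D numeric array `(x, y, z, time)`.
#' @param tissue_mask,background_mask Disjoint non-empty 3D masks.
#' @return A single SNR value; `Inf` when the background is exactly noise-free.
#' @export
estimate_snr <- function(series, tissue_mask, background_mask) {
  stopifnot(is.array(series), length(dim(series)) == 4L)
  shape <- dim(series)[1:3]
  tissue_mask <- array(as.logical(tissue_mask), shape)
  background_mask <- array(as.logical(background_mask), shape)
  if (!any(tissue_mask) || !any(background_mask)) {
    stop("masks must be non-empty", call. = FALSE)
  }
  if (any(tissue_mask & background_mask)) {
    stop("tissue and background masks must be disjoint", call. = FALSE)
  }
  first <- series[, , , 1, drop = FALSE]
  sig <- mean(first[tissue_mask])
  nvox <- prod(shape)
  bgv <- matrix(series, nrow = nvox)[which(background_mask), , drop = FALSE]
  noise <- stats::sd(as.vector(bgv))
  if (noise == 0) return(Inf)
  sig / noise
}
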