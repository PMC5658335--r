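#' Relaxation decay parameters
#'
#' Container for the parameters of a mono- or biexponential relaxation decay
#' \deqn{S(t) = S_0 \sum_{i=1}^{M} a_i e^{-t/T_i},\qquad M \in \{1, 2\},}
#' where `t` is the spin-lock time (T1rho) or echo time (T2) in milliseconds.
#' For the biexponential case the two components are canonically ordered so
#' that `T_s <= T_l` ("short" and "long"); if supplied the other way round the
#' components are swapped at construction. `T_s == T_l` is degenerate (the
#' model collapses to a monoexponential) and is refused.
#'
#' @param S0 Initial amplitude at `t = 0` (dimensionless, `> 0`). The Monte
#'   Carlo machinery assumes `S0 = 1`; fitting estimates it freely.
#' @param T_mono Monoexponential time constant in ms (mono only).
#' @param a_s,a_l Component amplitudes (dimensionless, `>= 0`, not both 0).
#' @param T_s,T_l Short and long time constants in ms (bi only).
#' @return An object of class `decay_params`: a list with `S0`,
#'   `n_components`, and either `T_mono` or `a_s, T_s, a_l, T_l`.
#' @examples
#' decay_params(T_mono = 26.9)
#' decay_params(a_s = 0.25, T_s = 6.3, a_l = 0.75, T_l = 37)
#' @export
decay_params <- function(S0 = 1, T_mono = NULL, a_s = NULL, T_s = NULL,
                         a_l = NULL, T_l = NULL) {
  stopifnot(is.numeric(S0), length(S0) == 1L, is.finite(S0))
  if (S0 <= 0) stop("`S0` must be > 0", call. = FALSE)
  bi_args <- list(a_s = a_s, T_s = T_s, a_l = a_l, T_l = T_l)
  if (!is.null(T_mono)) {
    if (any(!vapply(bi_args, is.null, logical(1)))) {
      stop("supply either `T_mono` or the biexponential quadruple, not both",
           call. = FALSE)
    }
    if (!is.finite(T_mono) || T_mono <= 0) {
      stop("time constant `T_mono` must be finite and > 0", call. = FALSE)
    }
    out <- list(S0 = S0, n_components = 1L, T_mono = T_mono)
  } else {
    if (any(vapply(bi_args, is.null, logical(1)))) {
      stop("biexponential parameters require all of `a_s`, `T_s`, `a_l`, `T_l`",
           call. = FALSE)
    }
    if (!all(vapply(bi_args, is.finite, logical(1)))) {
      stop("biexponential parameters must be finite", call. = FALSE)
    }
    if (a_s < 0 || a_l < 0) stop("amplitudes must be >= 0", call. = FALSE)
    if (a_s + a_l <= 0) stop("amplitudes must not both be zero", call. = FALSE)
    if (T_s <= 0 || T_l <= 0) stop("time constants must be > 0", call. = FALSE)
    if (T_s > T_l) {  # canonical ordering: swap components
      tmp <- list(a_s = a_l, T_s = T_l, a_l = a_s, T_l = T_s)
      a_s <- tmp$a_s; T_s <- tmp$T_s; a_l <- tmp$a_l; T_l <- tmp$T_l
    }
    if (T_s == T_l) {
      stop("`T_s` == `T_l` is degenerate: use a monoexponential `decay_params`",
           call. = FALSE)
    }
    out <- list(S0 = S0, n_components = 2L,
                a_s = a_s, T_s = T_s, a_l = a_l, T_l = T_l)
  }
  structure(out, class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  if (x$n_components == 1L) {
    cat(sprintf("<decay_params> mono: S0 = %g, T = %g ms\n", x$S0, x$T_mono))
  } else {
    fr <- fractions_from_amplitudes(x$a_s, x$a_l)
    cat(sprintf(
      "<decay_params> bi: S0 = %g, T_s = %g ms (F_s = %.3g%%), T_l = %g ms (F_l = %.3g%%)\n",
      x$S0, x$T_s, fr$F_s, x$T_l, fr$F_l))
  }
  invisible(x)
}

#' Acquisition schedule
#'
#' The ordered sample times of a relaxometry series: spin-lock times (TSL) for
#' T1rho imaging or echo times (TE) for T2 imaging, in milliseconds, plus a
#' modality tag and an optional nominal SNR. The study protocol uses 10 points
#' at 2, 4, 6, 8, 10, 15, 25, 35, 45 and 55 ms.
#'
#' @param times Numeric vector of sample times in ms, strictly increasing,
#'   all positive.
#' @param modality `"T1rho"` or `"T2"`.
#' @param snr Optional nominal signal-to-noise ratio (`SNR = 1/sigma` for unit
#'   initial signal).
#' @return An `acq_schedule` object.
#' @examples
#' protocol_schedule("T1rho")
#' acq_schedule(c(5, 10, 20, 40, 80), "T2")
#' @export
acq_schedule <- function(times, modality = c("T1rho", "T2"), snr = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("schedule times must be finite and > 0 (ms)", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("schedule times must be strictly increasing", call. = FALSE)
  }
  if (any(times > 1000)) {
    stop("schedule times exceed 1000 ms; times are expected in milliseconds, ",
         "not seconds", call. = FALSE)
  }
  if (!is.null(snr)) stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  structure(list(times = as.numeric(times), modality = modality, snr = snr),
            class = "acq_schedule")
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("<acq_schedule> %s, %d points: %s ms%s\n", x$modality,
              length(x$times), paste(x$times, collapse = ", "),
              if (is.null(x$snr)) "" else sprintf(" (nominal SNR %g)", x$snr)))
  invisible(x)
}

#' @rdname acq_schedule
#' @details `protocol_schedule()` returns the study's 10-point protocol with
#'   the in-vivo nominal SNR (65 for T1rho, 76 for T2).
#' @export
protocol_schedule <- function(modality = c("T1rho", "T2")) {
  modality <- match.arg(modality)
  acq_schedule(c(2, 4, 6, 8, 10, 15, 25, 35, 45, 55), modality,
               snr = if (modality == "T1rho") 65 else 76)
}

#' Monoexponential relaxation signal
#'
#' Evaluates \eqn{S(t) = S_0 e^{-t/T}} at the given times.
#'
#' @param t Times in ms (vectorised), `>= 0`.
#' @param params A monoexponential [decay_params()].
#' @return Numeric vector of signal values.
#' @examples
#' mono_signal(c(0, 27), decay_params(T_mono = 27))
#' @export
mono_signal <- function(t, params) {
  stopifnot(inherits(params, "decay_params"))
  if (params$n_components != 1L) {
    stop("`params` must be monoexponential (n_components = 1)", call. = FALSE)
  }
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  params$S0 * exp(-t / params$T_mono)
}

#' Biexponential relaxation signal
#'
#' Evaluates \eqn{S(t) = S_0 (a_s e^{-t/T_s} + a_l e^{-t/T_l})} at the given
#' times. With `a_s = 0` this reduces exactly to the monoexponential model
#' with `T = T_l`.
#'
#' @param t Times in ms (vectorised), `>= 0`.
#' @param params A biexponential [decay_params()].
#' @return Numeric vector of signal values.
#' @examples
#' p <- decay_params(a_s = 0.22, T_s = 4.6, a_l = 0.78, T_l = 33.2)
#' bi_signal(c(0, 10, 55), p)
#' @export
bi_signal <- function(t, params) {
  stopifnot(inherits(params, "decay_params"))
  if (params$n_components != 2L) {
    stop("`params` must be biexponential (n_components = 2)", call. = FALSE)
  }
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  params$S0 * (params$a_s * exp(-t / params$T_s) +
               params$a_l * exp(-t / params$T_l))
}

#' Evaluate a decay model at given times
#'
#' Dispatches to [mono_signal()] or [bi_signal()] on `n_components`.
#'
#' @inheritParams mono_signal
#' @return Numeric vector of signal values.
#' @export
decay_signal <- function(t, params) {
  if (params$n_components == 1L) mono_signal(t, params) else bi_signal(t, params)
}

#' Component fractions from amplitudes
#'
#' Converts the biexponential amplitudes into percentage fractions,
#' \eqn{F_l = 100\, a_l / (a_l + a_s)} and \eqn{F_s = 100\, a_s / (a_l + a_s)},
#' which sum to 100 by construction.
#'
#' @param a_s,a_l Non-negative amplitudes, not both zero.
#' @return A list with `F_s` and `F_l` in percent.
#' @examples
#' fractions_from_amplitudes(0.22, 0.78)  # 22 / 78
#' @export
fractions_from_amplitudes <- function(a_s, a_l) {
  stopifnot(is.numeric(a_s), is.numeric(a_l))
  if (any(a_s < 0) || any(a_l < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  tot <- a_s + a_l
  if (any(tot <= 0)) {
    stop("degenerate amplitudes: `a_s + a_l` must be > 0", call. = FALSE)
  }
  list(F_s = 100 * a_s / tot, F_l = 100 * a_l / tot)
}
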