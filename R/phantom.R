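# Synthetic calf-muscle phantom: five muscle ROIs (GM, GL, SOL, PER, TA) on
# a small 3D grid, each voxel mono- or biexponential with parameters drawn
# around the in-vivo per-ROI estimates, sampled at the acquisition schedule
# and corrupted with Gaussian noise. Stands in for non-public scanner data.

.roi_levels <- c("background", "GM", "GL", "SOL", "PER", "TA")

# Per-ROI in-vivo estimates (mean / sd) and the share of voxels with a valid
# biexponential fit ("ratio"), per modality.
.roi_tables <- list(
  T1rho = tibble::tribble(
    ~roi,  ~T_mono, ~T_mono_sd, ~T_s, ~T_s_sd, ~F_s, ~F_s_sd, ~T_l, ~T_l_sd, ~bi_fraction,
    "GM",   28, 1.5, 6.1, 0.6, 21, 1.5,  36,  2.3, 0.30,
    "GL",   28, 2.2, 7.8, 2.9, 25, 15,   42, 11,   0.22,
    "SOL",  29, 1.0, 6.4, 0.6, 21, 2.5,  37,  2.3, 0.30,
    "PER",  28, 2.6, 6.2, 1.3, 26, 10,   37,  5.0, 0.32,
    "TA",   25, 1.0, 6.2, 0.4, 31, 5.8,  37,  1.3, 0.28),
  T2 = tibble::tribble(
    ~roi,  ~T_mono, ~T_mono_sd, ~T_s, ~T_s_sd, ~F_s, ~F_s_sd, ~T_l, ~T_l_sd, ~bi_fraction,
    "GM",   25, 0.9, 6.3, 0.7, 18,  4.5, 34, 2.6, 0.18,
    "GL",   26, 1.1, 5.9, 0.8, 15,  3.7, 33, 3.5, 0.17,
    "SOL",  26, 0.6, 5.6, 0.3, 16,  2.4, 33, 1.1, 0.16,
    "PER",  25, 2.2, 5.9, 1.0, 22, 15,   35, 8.2, 0.20,
    "TA",   23, 2.2, 6.8, 1.0, 30, 10,   39, 5.3, 0.14))

#' Phantom specification
#'
#' Describes a synthetic relaxometry phantom: the voxel grid, a per-ROI
#' parameter table, the acquisition schedule and the noise level.
#'
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param roi_params Data frame with one row per ROI and columns `roi`,
#'   `T_mono`, `T_mono_sd`, `T_s`, `T_s_sd`, `F_s`, `F_s_sd` (percent),
#'   `T_l`, `T_l_sd`, `bi_fraction` (0--1: share of voxels that decay
#'   biexponentially).
#' @param schedule An [acq_schedule()].
#' @param noise A [noise_spec()].
#' @param bi_fraction Optional single value overriding every ROI's
#'   `bi_fraction`.
#' @return A `phantom_spec` object.
#' @seealso [default_phantom_spec()] for the study-default spec,
#'   [generate_phantom()] to realise it.
#' @export
phantom_spec <- function(grid_shape, roi_params, schedule, noise,
                         bi_fraction = NULL) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  need <- c("roi", "T_mono", "T_mono_sd", "T_s", "T_s_sd", "F_s", "F_s_sd",
            "T_l", "T_l_sd", "bi_fraction")
  stopifnot(is.data.frame(roi_params), all(need %in% names(roi_params)))
  if (!is.null(bi_fraction)) roi_params$bi_fraction <- bi_fraction
  if (any(roi_params$bi_fraction < 0 | roi_params$bi_fraction > 1)) {
    stop("`bi_fraction` must be in [0, 1]", call. = FALSE)
  }
  with(roi_params, {
    if (any(T_s < .bi_bounds$T_s[1] | T_s > .bi_bounds$T_s[2]) ||
        any(T_l < .bi_bounds$T_l[1] | T_l > .bi_bounds$T_l[2])) {
      stop("ROI time constants fall outside the fitting bounds", call. = FALSE)
    }
    if (any(4 * T_s >= T_l)) {
      stop("ROI mean components violate the separation condition 4*T_s < T_l",
           call. = FALSE)
    }
  })
  stopifnot(inherits(schedule, "acq_schedule"), inherits(noise, "noise_spec"))
  structure(list(grid_shape = as.integer(grid_shape),
                 roi_params = tibble::as_tibble(roi_params),
                 schedule = schedule, noise = noise),
            class = "phantom_spec")
}

#' Study-default phantom specification
#'
#' The default phantom emulates the study acquisition: the 10-point protocol
#' schedule (2--55 ms), Gaussian noise at the in-vivo SNR (65 for T1rho,
#' 76 for T2), and the five calf muscles parameterised by the per-ROI
#' in-vivo estimates. The grid defaults to 64 x 64 x 5 (five consecutive
#' slices, matrix scaled down from the scanner's 256 x 128).
#'
#' @param modality `"T1rho"` or `"T2"`.
#' @param grid_shape Voxel grid dimensions.
#' @param bi_fraction Optional override of every ROI's biexponential voxel
#'   share (e.g. `0.30` for the global T1rho rate).
#' @param snr Optional override of the nominal SNR; `Inf` gives a noiseless
#'   phantom.
#' @return A `phantom_spec`.
#' @examples
#' default_phantom_spec("T1rho")$schedule$times
#' @export
default_phantom_spec <- function(modality = c("T1rho", "T2"),
                                 grid_shape = c(64, 64, 5),
                                 bi_fraction = NULL, snr = NULL) {
  modality <- match.arg(modality)
  sch <- protocol_schedule(modality)
  if (!is.null(snr)) sch$snr <- if (is.finite(snr)) snr else NULL
  nz <- if (!is.null(snr) && !is.finite(snr)) noise_spec(sigma = 0)
        else noise_spec(snr = if (is.null(sch$snr)) 65 else sch$snr)
  phantom_spec(grid_shape, .roi_tables[[modality]], sch, nz,
               bi_fraction = bi_fraction)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s, %d ROIs, %s\n",
              paste(x$grid_shape, collapse = "x"), nrow(x$roi_params),
              x$schedule$modality))
  print(x$schedule); print(x$noise)
  invisible(x)
}

# 5 vertical ROI strips inside a 1-voxel background border (wider grids get
# a proportional border). Returns an integer array indexed into .roi_levels.
.roi_layout <- function(grid_shape, rois) {
  lab <- array(1L, grid_shape)  # 1 = background
  bx <- max(1L, round(grid_shape[1] * 0.1))
  by <- max(1L, round(grid_shape[2] * 0.1))
  xin <- (bx + 1L):(grid_shape[1] - bx)
  yin <- (by + 1L):(grid_shape[2] - by)
  cuts <- floor(seq(0, length(xin), length.out = length(rois) + 1L))
  for (k in seq_along(rois)) {
    xs <- xin[(cuts[k] + 1L):cuts[k + 1L]]
    lab[xs, yin, ] <- match(rois[k], .roi_levels)
  }
  lab
}

# truncated-normal draw via inverse CDF (deterministic under the global RNG)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic phantom
#'
#' Realises a [phantom_spec()]: assigns each ROI voxel a mono or
#' biexponential decay (Bernoulli with the ROI's `bi_fraction`), draws its
#' parameters from the ROI mean +/- SD (truncated to the fitting bounds,
#' with `T_s < T_l` enforced), evaluates the signal at the schedule times
#' with `S0 = 1`, and adds noise. Background voxels contain pure noise.
#' Fully reproducible under `seed`.
#'
#' @param spec A `phantom_spec`.
#' @param seed Integer seed.
#' @return A `phantom` object: `series` (4D array, x-y-z-time),
#'   `label_map` (3D integer array; 1 = background, then ROIs in spec
#'   order), `truth` (tibble: one row per tissue voxel with `x, y, z`,
#'   `roi`, `label` mono/bi and the generating parameters), `spec`, `seed`.
#' @examples
#' ph <- generate_phantom(default_phantom_spec("T1rho", c(16, 16, 1)), seed = 7)
#' dplyr::count(ph$truth, roi, label)
#' @export
generate_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  shape <- spec$grid_shape
  rois <- spec$roi_params$roi
  lab <- .roi_layout(shape, rois)
  t <- spec$schedule$times
  nt <- length(t)
  nvox <- prod(shape)
  sig <- matrix(0, nvox, nt)

  truth <- purrr::map_dfr(seq_along(rois), function(k) {
    row <- spec$roi_params[k, ]
    idx <- which(lab == match(rois[k], .roi_levels))
    n <- length(idx)
    if (n == 0L) return(NULL)
    is_bi <- stats::runif(n) < row$bi_fraction
    T_mono <- .rtruncnorm(n, row$T_mono, row$T_mono_sd, 0.5, .mono_T_max)
    T_s <- .rtruncnorm(n, row$T_s, row$T_s_sd,
                       .bi_bounds$T_s[1], .bi_bounds$T_s[2])
    T_l <- .rtruncnorm(n, row$T_l, row$T_l_sd,
                       pmax(.bi_bounds$T_l[1], T_s * 1.05), .bi_bounds$T_l[2])
    F_s <- .rtruncnorm(n, row$F_s, row$F_s_sd, 1, 99)
    for (j in seq_len(n)) {
      sig[idx[j], ] <<- if (is_bi[j]) {
        (F_s[j] / 100) * exp(-t / T_s[j]) + (1 - F_s[j] / 100) * exp(-t / T_l[j])
      } else {
        exp(-t / T_mono[j])
      }
    }
    co <- arrayInd(idx, shape)
    tibble::tibble(
      x = co[, 1], y = co[, 2], z = co[, 3], voxel = idx, roi = rois[k],
      label = ifelse(is_bi, "bi", "mono"),
      T_mono = ifelse(is_bi, NA_real_, T_mono),
      T_s = ifelse(is_bi, T_s, NA_real_),
      T_l = ifelse(is_bi, T_l, NA_real_),
      F_s = ifelse(is_bi, F_s, NA_real_))
  })

  if (spec$noise$sigma > 0) {
    eps <- matrix(stats::rnorm(nvox * nt, 0, spec$noise$sigma), nvox, nt)
    # Gaussian noise is left unclipped (at these SNRs tissue signal never
    # goes negative; the background keeps the full noise distribution, so
    # SNR estimation from background SD is unbiased)
    sig <- if (spec$noise$model == "rician") {
      sqrt((sig + eps)^2 +
             matrix(stats::rnorm(nvox * nt, 0, spec$noise$sigma), nvox, nt)^2)
    } else {
      sig + eps
    }
  }
  structure(list(series = array(sig, c(shape, nt)), label_map = lab,
                 truth = dplyr::arrange(truth, .data$voxel),
                 spec = spec, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> grid %s, %d tissue voxels (%.1f%% biexponential), seed %d\n",
              paste(x$spec$grid_shape, collapse = "x"), nrow(x$truth),
              100 * mean(x$truth$label == "bi"), x$seed))
  invisible(x)
}

#' Phantom tissue mask
#'
#' @param phantom A `phantom`.
#' @return Logical 3D array, `TRUE` at muscle voxels.
#' @export
phantom_tissue_mask <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  phantom$label_map > 1L
}

#' Long signal table of a phantom
#'
#' Reshapes the phantom's tissue signal into the tidy long format consumed
#' by [fit_voxels()].
#'
#' @param phantom A `phantom`.
#' @return Tibble with columns `voxel`, `roi`, `time`, `signal`.
#' @export
phantom_signals <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  t <- phantom$spec$schedule$times
  nvox <- prod(phantom$spec$grid_shape)
  mat <- matrix(phantom$series, nrow = nvox)
  phantom$truth |>
    dplyr::select("voxel", "roi") |>
    dplyr::mutate(signal = purrr::map(.data$voxel, function(v) {
      tibble::tibble(time = t, signal = mat[v, ])
    })) |>
    tidyr::unnest("signal")
}
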