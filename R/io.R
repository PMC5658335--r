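# NIfTI and config I/O: 4D series in, one NIfTI per parameter map out, with
# a JSON provenance sidecar; schedules as YAML.

#' Read a 4D relaxometry series
#'
#' Reads a NIfTI file (plain or gzipped) and checks it is 4-dimensional,
#' ordered `(x, y, z, time)`. The NIfTI header (affine, voxel sizes) is kept
#' on the returned object so maps written from it inherit the geometry.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An `RNifti` image array with 4 dimensions.
#' @export
read_relaxation_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) != 4L) {
    stop(path, " is ", length(dim(img)), "-dimensional; a 4D series ",
         "(x, y, z, time) is required", call. = FALSE)
  }
  img
}

#' Read a 3D mask or label volume
#'
#' @param path Path to a 3D NIfTI file.
#' @return An `RNifti` image array with 3 dimensions.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop(path, " must be a 3D volume", call. = FALSE)
  }
  img
}

#' Write parameter maps as NIfTI files
#'
#' Writes one NIfTI per map (`T_mono`, `T_short`, `T_long`, `F_short`,
#' `F_long`, `exclusion_mask`, `bi_detected`) plus a JSON provenance sidecar
#' recording the modality, grid, seed, package version and a hash of the
#' run configuration. Missing values are written as `NaN`; masks as 0/1.
#'
#' @param maps A `parameter_maps` object.
#' @param out_dir Output directory (created if absent).
#' @param geometry Optional reference image (e.g. from
#'   [read_relaxation_series()]) whose NIfTI geometry the maps inherit.
#' @param seed Optional seed to record in the sidecar.
#' @param config Optional list of run settings, hashed into the sidecar.
#' @return Invisibly, the vector of files written.
#' @export
write_parameter_maps <- function(maps, out_dir, geometry = NULL, seed = NULL,
                                 config = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map_names <- c("T_mono", "T_short", "T_long", "F_short", "F_long",
                 "exclusion_mask", "bi_detected")
  files <- character(0)
  for (nm in map_names) {
    m <- maps[[nm]]
    if (nm %in% c("exclusion_mask", "bi_detected")) {
      m[is.na(m)] <- 0  # binary maps: unknown -> 0
    }
    img <- if (is.null(geometry)) RNifti::asNifti(m) else
      RNifti::asNifti(m, reference = geometry)
    f <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  sidecar <- list(
    modality = maps$modality,
    grid_shape = maps$grid_shape,
    alpha = maps$alpha,
    n_fitted = maps$n_fitted,
    n_failed = maps$n_failed,
    seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("birelax")))
  sc <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(sidecar, sc, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(files, sc))
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param dir Directory containing the map files.
#' @return A `parameter_maps` object (tissue mask reconstructed as the
#'   voxels with a finite `T_mono` or a defined exclusion flag).
#' @export
read_parameter_maps <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "provenance.json"),
                            simplifyVector = TRUE)
  shape <- as.integer(sc$grid_shape)
  rd <- function(nm) {
    # NIfTI drops trailing singleton dimensions; restore the sidecar shape
    a <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    array(as.numeric(a), shape)
  }
  maps <- lapply(stats::setNames(nm = c("T_mono", "T_short", "T_long",
                                        "F_short", "F_long",
                                        "exclusion_mask", "bi_detected")), rd)
  tissue <- is.finite(maps$T_mono)
  structure(c(maps, list(tissue_mask = tissue, modality = sc$modality,
                         grid_shape = dim(maps$T_mono),
                         n_fitted = sc$n_fitted, n_failed = sc$n_failed,
                         alpha = sc$alpha)),
            class = "parameter_maps")
}

#' Read or write an acquisition schedule as YAML
#'
#' The YAML config lists `times` (ms), `modality` and optionally `snr`.
#' Times above 1000 ms are rejected with a hint that milliseconds are
#' expected.
#'
#' @param path YAML file path.
#' @return [read_schedule()]: an [acq_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$times) || is.null(cfg$modality)) {
    stop("schedule config needs `times` and `modality`", call. = FALSE)
  }
  acq_schedule(as.numeric(cfg$times), cfg$modality,
               snr = if (!is.null(cfg$snr)) as.numeric(cfg$snr))
}

#' @rdname read_schedule
#' @param schedule An [acq_schedule()] to write.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "acq_schedule"))
  yaml::write_yaml(list(times = schedule$times, modality = schedule$modality,
                        snr = schedule$snr), path)
  invisible(path)
}

#' Write a phantom to disk
#'
#' Writes the 4D series and the ROI label map as NIfTI plus a YAML sidecar
#' with the generating spec (schedule, noise, ROI table, seed). The voxel
#' truth table is written as CSV.
#'
#' @param phantom A `phantom`.
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_phantom <- function(phantom, out_dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_series <- file.path(out_dir, "series.nii.gz")
  f_labels <- file.path(out_dir, "labels.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$series), f_series)
  RNifti::writeNifti(RNifti::asNifti(phantom$label_map), f_labels)
  f_truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(phantom$truth, f_truth, row.names = FALSE)
  spec <- phantom$spec
  f_spec <- file.path(out_dir, "spec.yaml")
  yaml::write_yaml(list(
    grid_shape = spec$grid_shape,
    schedule = list(times = spec$schedule$times,
                    modality = spec$schedule$modality, snr = spec$schedule$snr),
    noise = list(model = spec$noise$model, sigma = spec$noise$sigma),
    roi_params = lapply(seq_len(nrow(spec$roi_params)),
                        function(i) as.list(spec$roi_params[i, ])),
    roi_levels = .roi_levels,
    seed = phantom$seed), f_spec)
  invisible(c(f_series, f_labels, f_truth, f_spec))
}
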