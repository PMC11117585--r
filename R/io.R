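# Dataset readers/writers and run configuration.
#
# On disk a dataset is a directory of 8-bit grayscale PNG slices plus a
# manifest CSV with one row per (subject, slice, volume). In memory images
# are floating point in [0, 1]; the generator quantizes to 8-bit levels so a
# write/load round trip preserves pixels exactly.

manifest_required_cols <- c("subject_id", "class", "scanner_id", "slice_idx",
                            "volume_idx", "slice_thickness_mm",
                            "pixel_spacing_x_mm", "pixel_spacing_y_mm", "path")

#' Write a slice dataset to PNG files + manifest
#'
#' @param ds A \code{slice_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  m <- ds$manifest
  m$path <- sprintf("images/%s_s%02d_v%03d_%d.png", m$subject_id, m$slice_idx,
                    m$volume_idx, seq_len(nrow(m)))
  for (i in seq_len(nrow(m))) {
    png::writePNG(ds$images[, , i], file.path(dir, m$path[i]))
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(m, mp, row.names = FALSE)
  invisible(mp)
}

#' Load a slice dataset from a manifest
#'
#' Reads the manifest CSV, validates it (required columns, no duplicate
#' (subject, slice, volume) keys, image files present and of one size) and
#' loads the grayscale PNGs as arrays in \eqn{[0, 1]}.
#'
#' @param manifest_path Path to \code{manifest.csv}; image paths are resolved
#'   relative to its directory.
#' @return A \code{slice_dataset}.
#' @export
load_dataset <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(manifest_required_cols, names(m))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(m$subject_id, m$slice_idx, m$volume_idx)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, slice, volume) keys at manifest row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  base <- dirname(manifest_path)
  files <- file.path(base, m$path)
  absent <- which(!file.exists(files))
  if (length(absent)) {
    stop("missing image file(s) for manifest row(s): ",
         paste(absent, collapse = ", "))
  }
  first <- png::readPNG(files[1])
  h <- dim(first)[1]; w <- dim(first)[2]
  images <- array(0, c(h, w, nrow(m)))
  for (i in seq_len(nrow(m))) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (!all(dim(img) == c(h, w))) {
      stop("image shape mismatch at manifest row ", i)
    }
    images[, , i] <- img
  }
  structure(list(images = images, manifest = m, spec = NULL),
            class = "slice_dataset")
}

#' Expand a 4D NIfTI volume into slice records
#'
#' Reads a 4D (X, Y, Z, T) NIfTI file and expands it to one record per
#' (slice, volume), with voxel metadata taken from the header's pixdim.
#' Intensities are rescaled to \eqn{[0, 1]} over the volume.
#'
#' @param path NIfTI file path.
#' @param subject_id,class,scanner_id Manifest fields for the subject.
#' @return A \code{slice_dataset}.
#' @export
load_nifti_volume <- function(path, subject_id, class, scanner_id) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI support requires the RNifti package")
  }
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) == 3L) { dim(vol) <- c(d, 1L); d <- dim(vol) }
  if (length(d) != 4L) stop("expected a 3D or 4D NIfTI volume")
  pd <- RNifti::pixdim(vol)
  rng <- range(vol)
  v <- if (diff(rng) > 0) (vol - rng[1]) / diff(rng) else vol * 0
  n <- d[3] * d[4]
  images <- array(0, c(d[1], d[2], n))
  rows <- expand.grid(volume_idx = seq_len(d[4]), slice_idx = seq_len(d[3]))
  rows <- rows[order(rows$slice_idx, rows$volume_idx), ]
  for (i in seq_len(n)) {
    images[, , i] <- v[, , rows$slice_idx[i], rows$volume_idx[i]]
  }
  manifest <- data.frame(subject_id = subject_id, class = class,
                         scanner_id = scanner_id,
                         slice_idx = rows$slice_idx,
                         volume_idx = rows$volume_idx,
                         slice_thickness_mm = if (length(pd) >= 3) pd[3] else NA,
                         pixel_spacing_x_mm = pd[1],
                         pixel_spacing_y_mm = pd[2],
                         path = path, stringsAsFactors = FALSE)
  structure(list(images = images, manifest = manifest, spec = NULL),
            class = "slice_dataset")
}

# --- run configuration -----------------------------------------------------

run_config_known_keys <- list(
  dataset = c("preset", "n_pd", "n_control", "slices_per_subject", "volumes",
              "size", "class_effect_amplitude", "seed", "control_ratio",
              "scanner_null", "manifest"),
  arch = c("variant", "input_shape", "conv_filters", "fc_sizes", "dropout",
           "taps", "n_classes", "gru_hidden"),
  objective = c("kind", "lambda", "lambda1", "lambda2", "class_weights",
                "scanner_weights", "control_label", "l2", "bias",
                "width_majority", "width_minority"),
  train = c("optimizer", "batch_size", "epochs", "lr_policy", "base_lr",
            "max_lr", "half_cycle", "gamma", "lr", "lr_decay", "lr_step",
            "seed", "min_dc_batch", "augment", "n_runs"),
  output = c("dir", "tag"))

#' Read and validate a run configuration file
#'
#' YAML with the sections \code{dataset}, \code{arch}, \code{objective},
#' \code{train}, \code{output}. Unknown sections or keys are rejected rather
#' than silently ignored.
#'
#' @param path YAML file path.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad_sec <- setdiff(names(cfg), names(run_config_known_keys))
  if (length(bad_sec)) stop("unknown config section(s): ",
                            paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), run_config_known_keys[[sec]])
    if (length(bad)) stop("unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", "))
  }
  cfg
}

#' Write a self-describing run directory
#'
#' Creates \code{dir} with the config copy, the seeds used, the training log
#' as CSV and the metrics as JSON, so the run can be reproduced bit for bit
#' from the directory contents alone.
#'
#' @param dir Run directory.
#' @param config Configuration list (as from [read_run_config()]).
#' @param fit Optional fitted [dccnn()]; its history is written as CSV.
#' @param metrics Optional named list of metrics, written as JSON.
#' @return Invisibly, \code{dir}.
#' @export
write_run_dir <- function(dir, config, fit = NULL, metrics = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  if (!is.null(fit)) {
    utils::write.csv(fit$history, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = fit$control$seed,
                              n_params = fit$n_params,
                              val_ba = fit$val_ba),
                         file.path(dir, "run.json"), auto_unbox = TRUE)
  }
  if (!is.null(metrics)) {
    jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
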