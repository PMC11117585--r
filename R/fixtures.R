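# Synthetic two-class, multi-scanner slice phantoms.
#
# The generator emulates the statistical structure the decorrelation method
# assumes: a weak class effect (a focal intensity blob), scanner effects
# (smoothing, gain, static noise, distinct voxel-size metadata), an optional
# temporal axis with scanner-specific fluctuation amplitude, and severe class
# and scanner imbalance. Class and scanner effects are independent knobs so
# each can be switched off to build null datasets.

#' Scanner acquisition profile
#'
#' Bundles the image-level transform a scanner applies (smoothing, gain,
#' noise) with its acquisition metadata (slice thickness, pixel spacing).
#' Presets: \code{"ppmi_like"} (thickness 3.2999 mm, spacing 3.2941 mm, mild
#' smoothing, low temporal noise) and \code{"nifd_like"} (thickness 3.0 mm,
#' spacing 2.5 mm, heavier smoothing, higher gain, 3x the temporal noise).
#'
#' @param name Profile name or one of the presets above.
#' @param smoothing_sigma Gaussian smoothing applied by the scanner, in px.
#' @param gain Multiplicative intensity gain.
#' @param noise_sigma Static per-slice noise sd (intensity units, images in
#'   \eqn{[0,1]}).
#' @param temporal_noise_sigma Per-frame noise sd for temporal stacks.
#' @param slice_thickness_mm,pixel_spacing_mm Voxel metadata; spacing is
#'   \code{c(x, y)} in mm.
#' @return Object of class \code{scanner_profile}.
#' @export
scanner_profile <- function(name = "ppmi_like", smoothing_sigma = NULL,
                            gain = NULL, noise_sigma = NULL,
                            temporal_noise_sigma = NULL,
                            slice_thickness_mm = NULL,
                            pixel_spacing_mm = NULL) {
  preset <- switch(name,
    ppmi_like = list(smoothing_sigma = 1.0, gain = 1.0, noise_sigma = 0.06,
                     temporal_noise_sigma = 0.05,
                     slice_thickness_mm = 3.2999,
                     pixel_spacing_mm = c(3.2941, 3.2941)),
    nifd_like = list(smoothing_sigma = 1.8, gain = 1.25, noise_sigma = 0.10,
                     temporal_noise_sigma = 0.15,
                     slice_thickness_mm = 3.0,
                     pixel_spacing_mm = c(2.5, 2.5)),
    list(smoothing_sigma = 1.0, gain = 1.0, noise_sigma = 0.06,
         temporal_noise_sigma = 0.05, slice_thickness_mm = 3.0,
         pixel_spacing_mm = c(3.0, 3.0)))
  p <- list(name = name,
            smoothing_sigma = smoothing_sigma %||% preset$smoothing_sigma,
            gain = gain %||% preset$gain,
            noise_sigma = noise_sigma %||% preset$noise_sigma,
            temporal_noise_sigma = temporal_noise_sigma %||% preset$temporal_noise_sigma,
            slice_thickness_mm = slice_thickness_mm %||% preset$slice_thickness_mm,
            pixel_spacing_mm = pixel_spacing_mm %||% preset$pixel_spacing_mm)
  num <- c(p$smoothing_sigma, p$gain, p$noise_sigma, p$temporal_noise_sigma,
           p$slice_thickness_mm, p$pixel_spacing_mm)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("scanner profile parameters must be positive")
  }
  structure(p, class = "scanner_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort specification for the synthetic generator
#'
#' @param n_pd,n_control Subject counts per class (defaults give the 9:1
#'   imbalance of the single-scanner design).
#' @param slices_per_subject Slices rendered per subject, default 5.
#' @param volumes Temporal frames T per slice, default 1 (no temporal axis).
#' @param size Image size \code{c(H, W)}, default 66 x 66.
#' @param class_effect_amplitude Mean intensity amplitude of the focal
#'   disease blob for PD subjects; 0 gives a class-null dataset.
#' @param class_effect_sd Between-subject standard deviation of the blob
#'   amplitude (disease expression varies from person to person); applies to
#'   both classes, so the class distributions overlap.
#' @param control_effect_frac Control subjects draw their blob amplitude
#'   around \code{control_effect_frac * class_effect_amplitude}.
#' @param class_effect_region \code{c(row, col, sigma)} in px; default places
#'   the blob inside the phantom.
#' @param seed Master seed; everything downstream is deterministic in it.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_pd = 90L, n_control = 10L, slices_per_subject = 5L,
                        volumes = 1L, size = c(66L, 66L),
                        class_effect_amplitude = 0.25,
                        class_effect_sd = 0.08,
                        control_effect_frac = 0.3,
                        class_effect_region = NULL, seed = 1L) {
  size <- as.integer(size)
  if (is.null(class_effect_region)) {
    class_effect_region <- c(round(0.60 * size[1]), round(0.55 * size[2]), 6)
  }
  structure(list(n_pd = as.integer(n_pd), n_control = as.integer(n_control),
                 slices_per_subject = as.integer(slices_per_subject),
                 volumes = as.integer(volumes), size = size,
                 class_effect_amplitude = class_effect_amplitude,
                 class_effect_sd = class_effect_sd,
                 control_effect_frac = control_effect_frac,
                 class_effect_region = class_effect_region,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Elliptical brain mask of a phantom slice.
phantom_mask <- function(h, w) {
  r <- matrix(seq_len(h), h, w); c2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - h / 2) / (0.42 * h))^2 + ((c2 - w / 2) / (0.38 * w))^2 <= 1
}

gauss_blob <- function(h, w, row, col, sigma) {
  r <- matrix(seq_len(h), h, w); c2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  exp(-((r - row)^2 + (c2 - col)^2) / (2 * sigma^2))
}

# Separable Gaussian smoothing as banded Toeplitz products, renormalized at
# the borders; exact for any image size (no minimum-kernel constraint).
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    idx <- seq_len(n)
    k <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Render one subject's slice stack
#'
#' Builds an elliptical brain phantom with smooth per-subject texture, adds a
#' focal Gaussian blob for the disease class, then applies the scanner
#' transform (smoothing, gain, static noise). With \code{spec$volumes > 1},
#' each slice becomes a T-frame series with per-frame noise of the profile's
#' \code{temporal_noise_sigma}. Values are clipped to \eqn{[0,1]} and
#' quantized to 8-bit levels (the on-disk PNG convention).
#'
#' @param class \code{"PD"} or \code{"control"}.
#' @param profile A [scanner_profile()].
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed for this subject's randomness.
#' @return Array \code{(H, W, slices)} or \code{(H, W, slices, T)}.
#' @export
render_subject <- function(class, profile, spec, subject_seed) {
  h <- spec$size[1]; w <- spec$size[2]
  reg <- spec$class_effect_region
  mask <- phantom_mask(h, w)
  if (!mask[reg[1], reg[2]]) {
    stop("class effect region (", reg[1], ", ", reg[2], ") lies outside the phantom")
  }
  Tn <- spec$volumes
  out <- if (Tn > 1L) array(0, c(h, w, spec$slices_per_subject, Tn)) else
    array(0, c(h, w, spec$slices_per_subject))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(subject_seed)
  # smooth per-subject anatomy texture shared across slices
  tex <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), sigma = 4)
  tex <- 0.03 * tex / stats::sd(tex)
  # per-subject disease expression: overlapping class distributions (the
  # same normal draw is consumed for both classes, so a zero amplitude
  # yields byte-identical class-null renderings)
  sd_frac <- if (is.null(spec$class_effect_sd)) 0 else spec$class_effect_sd
  ctl_frac <- if (is.null(spec$control_effect_frac)) 0 else spec$control_effect_frac
  amp_mean <- if (class == "PD") spec$class_effect_amplitude else
    ctl_frac * spec$class_effect_amplitude
  amp <- max(0, amp_mean + sd_frac * stats::rnorm(1) *
               (spec$class_effect_amplitude != 0))
  for (s in seq_len(spec$slices_per_subject)) {
    # each slice carries its own smooth texture component on top of the
    # subject texture: neighbouring brain slices are similar, not copies
    tex_s <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), sigma = 3)
    tex_s <- 0.02 * tex_s / stats::sd(tex_s)
    base <- 0.5 * mask + (tex + tex_s) * mask
    base <- base - 0.18 * gauss_blob(h, w, h / 2, w / 2, 0.09 * h) * mask
    base <- base + 0.02 * stats::rnorm(1) # slice-level intensity jitter
    if (amp > 0) {
      base <- base + amp * gauss_blob(h, w, reg[1], reg[2], reg[3]) * mask
    }
    img <- gauss_smooth(base, profile$smoothing_sigma)
    img <- img * profile$gain +
      matrix(stats::rnorm(h * w, 0, profile$noise_sigma), h, w)
    if (Tn > 1L) {
      for (t in seq_len(Tn)) {
        fr <- img + matrix(stats::rnorm(h * w, 0, profile$temporal_noise_sigma), h, w)
        out[, , s, t] <- round(pmin(pmax(fr, 0), 1) * 255) / 255
      }
    } else {
      out[, , s] <- round(pmin(pmax(img, 0), 1) * 255) / 255
    }
  }
  out
}

subject_seed_for <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

# Assemble a slice_dataset from per-subject renderings.
assemble_dataset <- function(subjects, spec) {
  h <- spec$size[1]; w <- spec$size[2]
  Tn <- spec$volumes
  n_rec <- sum(vapply(subjects, function(s) spec$slices_per_subject * Tn, 0))
  images <- array(0, c(h, w, n_rec))
  rows <- vector("list", length(subjects))
  k <- 0L
  for (si in seq_along(subjects)) {
    su <- subjects[[si]]
    idx <- integer(0)
    for (s in seq_len(spec$slices_per_subject)) {
      for (t in seq_len(Tn)) {
        k <- k + 1L
        images[, , k] <- if (Tn > 1L) su$stack[, , s, t] else su$stack[, , s]
        idx <- c(idx, k)
      }
    }
    pr <- su$profile
    rows[[si]] <- data.frame(
      subject_id = su$subject_id, class = su$class, scanner_id = pr$name,
      slice_idx = rep(seq_len(spec$slices_per_subject), each = Tn),
      volume_idx = rep(seq_len(Tn), times = spec$slices_per_subject),
      slice_thickness_mm = pr$slice_thickness_mm,
      pixel_spacing_x_mm = pr$pixel_spacing_mm[1],
      pixel_spacing_y_mm = pr$pixel_spacing_mm[2],
      path = NA_character_, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  structure(list(images = images, manifest = manifest, spec = spec),
            class = "slice_dataset")
}

#' Generate a single-scanner imbalanced dataset
#'
#' The class-bias study condition: one scanner, PD:control subject ratio 9:1
#' by default, mirroring the slice-count imbalance of the motivating cohort.
#'
#' @param spec A [cohort_spec()]; \code{n_pd / n_control} must be >= 1.
#' @param profile The single [scanner_profile()].
#' @return A \code{slice_dataset}: images \code{(H, W, N)} in \eqn{[0,1]}
#'   plus a manifest data frame.
#' @export
generate_singlescanner_imbalanced <- function(spec = cohort_spec(),
                                              profile = scanner_profile("ppmi_like")) {
  if (spec$n_pd < spec$n_control) {
    stop("expected an imbalanced cohort with PD as the majority class")
  }
  classes <- c(rep("PD", spec$n_pd), rep("control", spec$n_control))
  subjects <- lapply(seq_along(classes), function(i) {
    list(subject_id = sprintf("S%03d", i), class = classes[i], profile = profile,
         stack = render_subject(classes[i], profile, spec,
                                subject_seed_for(spec$seed, i)))
  })
  assemble_dataset(subjects, spec)
}

#' Generate a two-scanner dataset with confounded class/scanner design
#'
#' The scanner-bias study condition: PD subjects appear on scanner A only,
#' while controls are scanned on both scanners with an imbalanced A:B ratio
#' (default 1:9). This is the configuration in which a plain classifier can
#' solve the class task through the scanner shortcut.
#'
#' @param spec A [cohort_spec()].
#' @param profiles Named list of two [scanner_profile()]s; the first is the
#'   PD scanner. Identical transform parameters give a scanner-null dataset.
#' @param control_ratio Ratio \code{c(A, B)} of control subjects across the
#'   two scanners, default \code{c(1, 9)}.
#' @param allow_pd_on_both Explicit override to also place PD on scanner B.
#' @return A \code{slice_dataset}.
#' @export
generate_multiscanner <- function(spec = cohort_spec(n_pd = 40L, n_control = 60L),
                                  profiles = list(
                                    ppmi = scanner_profile("ppmi_like"),
                                    nifd = scanner_profile("nifd_like")),
                                  control_ratio = c(1, 9),
                                  allow_pd_on_both = FALSE) {
  if (length(profiles) != 2L) stop("need exactly two scanner profiles")
  if (is.null(names(profiles))) names(profiles) <- c("A", "B")
  for (nm in names(profiles)) profiles[[nm]]$name <- nm
  nA <- max(1L, round(spec$n_control * control_ratio[1] / sum(control_ratio)))
  nB <- spec$n_control - nA
  if (nB < 1L) stop("control cohort too small for the requested ratio")
  cls <- c(rep("PD", spec$n_pd), rep("control", nA + nB))
  scn <- c(rep(1L, spec$n_pd), rep(1L, nA), rep(2L, nB))
  if (allow_pd_on_both && spec$n_pd >= 2L) {
    scn[seq_len(spec$n_pd %/% 2L)] <- 2L
  }
  subjects <- lapply(seq_along(cls), function(i) {
    pr <- profiles[[scn[i]]]
    list(subject_id = sprintf("S%03d", i), class = cls[i], profile = pr,
         stack = render_subject(cls[i], pr, spec, subject_seed_for(spec$seed, i)))
  })
  assemble_dataset(subjects, spec)
}

#' @export
print.slice_dataset <- function(x, ...) {
  m <- x$manifest
  cat("slice_dataset:", dim(x$images)[3], "images of",
      dim(x$images)[1], "x", dim(x$images)[2], "\n")
  cat("  subjects:", length(unique(m$subject_id)),
      " classes:", paste(sprintf("%s=%d", names(table(m$class)),
                                 as.integer(table(m$class))), collapse = " "),
      "\n")
  cat("  scanners:", paste(unique(m$scanner_id), collapse = ", "), "\n")
  if (!is.null(m$split)) {
    cat("  split:", paste(sprintf("%s=%d", names(table(m$split)),
                                  as.integer(table(m$split))), collapse = " "), "\n")
  }
  invisible(x)
}

#' Assign subject-grouped train/validation/test splits
#'
#' Adds a \code{split} column to the manifest, assigning whole subjects to
#' train/val/test (default 70/15/15) stratified by class and scanner, so no
#' subject's slices leak across splits.
#'
#' @param ds A \code{slice_dataset}.
#' @param props Split proportions summing to 1.
#' @param seed Seed for the assignment.
#' @return The dataset with \code{manifest$split} filled in.
#' @export
split_subjects <- function(ds, props = c(train = 0.7, val = 0.15, test = 0.15),
                           seed = 1L) {
  m <- ds$manifest
  subj <- unique(m[, c("subject_id", "class", "scanner_id")])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  subj$split <- NA_character_
  strata <- split(seq_len(nrow(subj)), paste(subj$class, subj$scanner_id))
  strata <- strata[sort(names(strata), method = "radix")]  # locale-independent
  for (g in strata) {
    n <- length(g)
    n_tr <- max(1L, round(props[1] * n))
    n_va <- max(1L, round(props[2] * n))
    while (n_tr + n_va >= n && n_tr > 1L) n_tr <- n_tr - 1L
    ord <- sample(g)
    lab <- c(rep("train", n_tr), rep("val", min(n_va, n - n_tr)),
             rep("test", max(0L, n - n_tr - min(n_va, n - n_tr))))
    subj$split[ord] <- lab
  }
  ds$manifest$split <- subj$split[match(m$subject_id, subj$subject_id)]
  ds
}

# Select manifest rows (and images) of a dataset; returns a slice_dataset.
subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[, , idx, drop = FALSE],
                 manifest = ds$manifest[idx, , drop = FALSE],
                 spec = ds$spec),
            class = "slice_dataset")
}

# Regroup a temporal dataset's frames into series: returns list(series =
# (H, W, T, M) array, manifest = one row per (subject, slice)).
get_timeseries <- function(ds) {
  m <- ds$manifest
  if (max(m$volume_idx) < 2L) stop("dataset has no temporal axis")
  key <- paste(m$subject_id, m$slice_idx)
  groups <- split(seq_len(nrow(m)), key)
  groups <- groups[sort(names(groups), method = "radix")]
  Tn <- max(m$volume_idx)
  h <- dim(ds$images)[1]; w <- dim(ds$images)[2]
  series <- array(0, c(h, w, Tn, length(groups)))
  rows <- integer(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]][order(m$volume_idx[groups[[i]]])]
    stopifnot(length(g) == Tn)
    series[, , , i] <- ds$images[, , g]
    rows[i] <- g[1]
  }
  sm <- m[rows, c("subject_id", "class", "scanner_id", "slice_idx",
                  "slice_thickness_mm", "pixel_spacing_x_mm",
                  "pixel_spacing_y_mm", if ("split" %in% names(m)) "split")]
  rownames(sm) <- NULL
  list(series = series, manifest = sm)
}
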