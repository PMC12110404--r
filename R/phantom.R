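#' Configuration for the synthetic tumor-phantom generator
#'
#' The phantom emulates the statistical situation of a two-class CT cohort
#' in which all class-discriminative signal lives inside a tumor-like
#' region of interest (ROI), while the background carries high-contrast
#' structures that are independent of the class label.  Each "patient"
#' contributes several slices sharing one lesion geometry; slices differ by
#' texture phase, background distractors and acquisition noise.
#'
#' The class signal has two independent knobs: a shift of the mean interior
#' intensity (`roi_contrast`, positive class brighter) and a class-dependent
#' speckle frequency of the interior texture (`roi_texture_freq`).  Setting
#' `roi_contrast = 0` and equal texture frequencies makes the label
#' statistically independent of the pixels.
#'
#' @param n_patients_per_class patients simulated per class.
#' @param slices_per_patient integer count, or length-2 range from which a
#'   per-patient count is drawn uniformly.
#' @param image_size side length in pixels of the square slice (>= 32).
#' @param roi_radius_range length-2 range, in pixels, of the ellipse
#'   semi-axes; sampled once per patient.
#' @param roi_contrast difference in mean interior intensity between the
#'   positive and negative class, in [0,1] intensity units.  The negative
#'   class interior sits at the background level, the positive class at
#'   background + `roi_contrast`.
#' @param roi_texture_freq length-2 vector: interior speckle frequency, in
#'   cycles per image width, for class 0 and class 1.
#' @param roi_texture_amp amplitude of the interior speckle texture.
#' @param background_distractor_count high-contrast background structures
#'   (blobs and bars) per slice; placed strictly outside the ROI and drawn
#'   independently of the label.
#' @param distractor_contrast length-2 range of absolute intensity offsets
#'   of the distractors.
#' @param distractor_layout `"patient"` (default): each patient has one
#'   fixed background layout recurring on all slices, as the surrounding
#'   anatomy does in a multi-slice scan; `"slice"`: distractors are drawn
#'   fresh for every slice.
#' @param noise_sigma standard deviation of the per-pixel Gaussian
#'   acquisition noise, in intensity units.
#' @param background_level base intensity of the background tissue.
#' @param roi_center_jitter per-patient displacement of the lesion center
#'   from the image center, as a fraction of the side length.
#' @param seed integer; every random draw of the generator flows from it.
#' @return object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_patients_per_class = 25,
                           slices_per_patient = c(3, 6),
                           image_size = 64,
                           roi_radius_range = c(8, 14),
                           roi_contrast = 0.15,
                           roi_texture_freq = c(6, 12),
                           roi_texture_amp = 0.08,
                           background_distractor_count = 6,
                           distractor_contrast = c(0.2, 0.45),
                           distractor_layout = c("patient", "slice"),
                           noise_sigma = 0.05,
                           background_level = 0.35,
                           roi_center_jitter = 0.1,
                           seed = 1L) {
  cfg <- list(
    n_patients_per_class = as.integer(n_patients_per_class),
    slices_per_patient = as.integer(slices_per_patient),
    image_size = as.integer(image_size),
    roi_radius_range = as.numeric(roi_radius_range),
    roi_contrast = as.numeric(roi_contrast),
    roi_texture_freq = as.numeric(roi_texture_freq),
    roi_texture_amp = as.numeric(roi_texture_amp),
    background_distractor_count = as.integer(background_distractor_count),
    distractor_contrast = as.numeric(distractor_contrast),
    distractor_layout = match.arg(distractor_layout),
    noise_sigma = as.numeric(noise_sigma),
    background_level = as.numeric(background_level),
    roi_center_jitter = as.numeric(roi_center_jitter),
    seed = as.integer(seed)
  )
  if (cfg$image_size < 32L) {
    stop("phantom configuration error: image_size must be >= 32", call. = FALSE)
  }
  if (cfg$n_patients_per_class < 1L) {
    stop("phantom configuration error: need at least one patient per class",
         call. = FALSE)
  }
  if (length(cfg$slices_per_patient) == 1L) {
    cfg$slices_per_patient <- rep(cfg$slices_per_patient, 2L)
  }
  if (cfg$roi_contrast < 0) {
    stop("phantom configuration error: roi_contrast must be >= 0", call. = FALSE)
  }
  if (length(cfg$roi_texture_freq) == 1L) {
    cfg$roi_texture_freq <- rep(cfg$roi_texture_freq, 2L)
  }
  max_extent <- max(cfg$roi_radius_range) +
    cfg$roi_center_jitter * cfg$image_size
  if (max_extent >= cfg$image_size / 2) {
    stop("phantom configuration error: ROI (radius + jitter) does not fit ",
         "inside the image", call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

#' Generate a patient-grouped phantom cohort
#'
#' Samples per-patient lesion geometry once (position, semi-axes), then
#' renders each slice with independent texture phase, distractors and
#' noise.  Deterministic given `config$seed`: the same configuration always
#' yields a bit-identical cohort.
#'
#' @param config a [phantom_config()].
#' @return object of class `drlroi_cohort`: a list with `samples` (each a
#'   list with `image`, `mask`, `label`, `patient_id`, `slice_id`),
#'   `class_counts` (patients per class) and the generating `config`.
#' @export
#' @examples
#' co <- phantom_cohort(phantom_config(n_patients_per_class = 2,
#'                                     slices_per_patient = 2,
#'                                     image_size = 32,
#'                                     roi_radius_range = c(5, 8)))
#' length(co$samples)  # 2 patients/class x 2 classes x 2 slices = 8
phantom_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, {
    samples <- list()
    pid <- 0L
    for (label in c(0L, 1L)) {
      for (p in seq_len(config$n_patients_per_class)) {
        pid <- pid + 1L
        geom <- sample_patient_geometry(config)
        n_slices <- if (config$slices_per_patient[1] ==
                        config$slices_per_patient[2]) {
          config$slices_per_patient[1]
        } else {
          sample(config$slices_per_patient[1]:config$slices_per_patient[2], 1L)
        }
        for (s in seq_len(n_slices)) {
          sl <- render_slice(label, geom, config)
          samples[[length(samples) + 1L]] <- list(
            image = sl$image, mask = sl$mask, label = label,
            patient_id = sprintf("P%03d", pid),
            slice_id = sprintf("P%03d_S%02d", pid, s)
          )
        }
      }
    }
    structure(
      list(samples = samples,
           class_counts = c(`0` = config$n_patients_per_class,
                            `1` = config$n_patients_per_class),
           config = config),
      class = "drlroi_cohort"
    )
  })
}

# Per-patient anatomy: lesion center with jitter, ellipse semi-axes, and
# the patient's background distractor layout.  Distractors are fixed per
# patient -- the same background structures recur on every slice of one
# "scan" -- which is what makes them a genuine confounder: a classifier
# can memorize patient-specific backgrounds that carry no class signal.
sample_patient_geometry <- function(config) {
  S <- config$image_size
  jit <- config$roi_center_jitter * S
  distractors <- lapply(seq_len(config$background_distractor_count),
                        function(d) {
    amp <- sample(c(-1, 1), 1) *
      stats::runif(1, config$distractor_contrast[1],
                   config$distractor_contrast[2])
    if (stats::runif(1) < 0.5) {
      list(type = "blob", amp = amp,
           cx = stats::runif(1, 0, S), cy = stats::runif(1, 0, S),
           rx = stats::runif(1, 2, S / 8), ry = stats::runif(1, 2, S / 8))
    } else {
      list(type = "bar", amp = amp,
           th = stats::runif(1, 0, pi), off = stats::runif(1, -S / 2, S / 2),
           width = stats::runif(1, 1, 3))
    }
  })
  list(
    cx = S / 2 + stats::runif(1, -jit, jit),
    cy = S / 2 + stats::runif(1, -jit, jit),
    rx = stats::runif(1, config$roi_radius_range[1], config$roi_radius_range[2]),
    ry = stats::runif(1, config$roi_radius_range[1], config$roi_radius_range[2]),
    distractors = distractors
  )
}

#' Render one phantom slice
#'
#' Interior intensity is `background_level + label * roi_contrast` plus a
#' zero-mean speckle texture whose frequency depends on the label; the
#' exterior is the background plus label-independent distractors; Gaussian
#' noise of sd `noise_sigma` is added everywhere and the image clipped to
#' [0,1].  The mask is true exactly on the ROI ellipse.
#'
#' Uses the current RNG state; callers wanting reproducibility seed first
#' (as [phantom_cohort()] does).
#'
#' @param label class in {0, 1}.
#' @param geometry list with `cx`, `cy` (ellipse center, pixels) and `rx`,
#'   `ry` (semi-axes, pixels).
#' @param config a [phantom_config()].
#' @return list with `image` (matrix in [0,1]) and `mask` (logical matrix).
#' @export
render_slice <- function(label, geometry, config) {
  S <- config$image_size
  if (geometry$cx - geometry$rx < 0 || geometry$cx + geometry$rx > S ||
      geometry$cy - geometry$ry < 0 || geometry$cy + geometry$ry > S) {
    stop("phantom configuration error: ROI extends outside the image",
         call. = FALSE)
  }
  xx <- matrix(rep(seq_len(S) - 0.5, S), S, S)        # row coordinate
  yy <- matrix(rep(seq_len(S) - 0.5, each = S), S, S) # column coordinate
  mask <- ((xx - geometry$cx) / geometry$rx)^2 +
    ((yy - geometry$cy) / geometry$ry)^2 <= 1

  img <- matrix(config$background_level, S, S)

  # Background distractors: high-contrast blobs and bars from the
  # patient's fixed layout (or drawn fresh if the geometry carries none),
  # masked to the ROI exterior so no class-relevant pixel is disturbed.
  distractors <- geometry$distractors
  if ((is.null(distractors) || identical(config$distractor_layout, "slice")) &&
      config$background_distractor_count > 0) {
    distractors <- sample_patient_geometry(config)$distractors
  }
  if (length(distractors)) {
    D <- matrix(0, S, S)
    for (d in distractors) {
      if (d$type == "blob") {
        hit <- ((xx - d$cx) / d$rx)^2 + ((yy - d$cy) / d$ry)^2 <= 1
      } else {
        u <- (xx - S / 2) * cos(d$th) + (yy - S / 2) * sin(d$th)
        v <- -(xx - S / 2) * sin(d$th) + (yy - S / 2) * cos(d$th)
        hit <- abs(u - d$off) <= d$width & abs(v) <= S / 2
      }
      D[hit] <- D[hit] + d$amp
    }
    D[mask] <- 0
    img <- img + D
  }

  # Class-dependent interior: mean shift plus speckle texture.
  freq <- config$roi_texture_freq[label + 1L]
  th <- stats::runif(1, 0, pi)
  ph <- stats::runif(1, 0, 2 * pi)
  tex <- config$roi_texture_amp *
    sin(2 * pi * freq * (cos(th) * xx + sin(th) * yy) / S + ph)
  img[mask] <- config$background_level + label * config$roi_contrast +
    tex[mask]

  if (config$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sigma), S, S)
  }
  list(image = clip01(img), mask = mask)
}

#' @export
print.drlroi_cohort <- function(x, ...) {
  man <- cohort_manifest(x)
  cat("phantom cohort:", length(unique(man$patient_id)), "patients,",
      nrow(man), "slices\n")
  cat("  patients per class:",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$config$image_size)) {
    cat("  image size:", x$config$image_size, "x", x$config$image_size, "\n")
  }
  invisible(x)
}

#' Tabular view of a cohort
#'
#' @param cohort a `drlroi_cohort`.
#' @return data.frame with columns `patient_id`, `slice_id`, `label`.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort$samples, `[[`, "", "patient_id"),
    slice_id = vapply(cohort$samples, `[[`, "", "slice_id"),
    label = vapply(cohort$samples, function(s) as.integer(s$label), 0L),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to disk as PNG slices plus a manifest
#'
#' Slices and masks are written as 8-bit grayscale PNG; the manifest CSV has
#' columns `patient_id`, `slice_id`, `image_path`, `mask_path`, `label`.
#' Note the 8-bit quantization: a round trip through disk is faithful to
#' about 1/255 in intensity.
#'
#' @param cohort a `drlroi_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$image_path <- file.path("images", paste0(man$slice_id, ".png"))
  man$mask_path <- file.path("masks", paste0(man$slice_id, "_mask.png"))
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    png::writePNG(s$image, file.path(dir, man$image_path[i]))
    png::writePNG(s$mask * 1.0, file.path(dir, man$mask_path[i]))
  }
  man <- man[, c("patient_id", "slice_id", "image_path", "mask_path", "label")]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest CSV written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV; image paths are resolved
#'   relative to its directory.
#' @return a `drlroi_cohort` (without a generator config).
#' @export
read_cohort <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  root <- dirname(manifest)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(root, man$image_path[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    msk <- png::readPNG(file.path(root, man$mask_path[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    list(image = img, mask = msk > 0.5, label = as.integer(man$label[i]),
         patient_id = man$patient_id[i], slice_id = man$slice_id[i])
  })
  labels <- vapply(samples, `[[`, 0L, "label")
  pids <- vapply(samples, `[[`, "", "patient_id")
  structure(
    list(samples = samples,
         class_counts = vapply(split(pids, labels),
                               function(p) length(unique(p)), 0L),
         config = NULL),
    class = "drlroi_cohort"
  )
}

# Build a cohort object from an explicit sample list (internal).
cohort_from_samples <- function(samples, config = NULL) {
  labels <- vapply(samples, `[[`, 0L, "label")
  pids <- vapply(samples, `[[`, "", "patient_id")
  counts <- vapply(split(pids, labels), function(p) length(unique(p)), 0L)
  structure(list(samples = samples, class_counts = counts, config = config),
            class = "drlroi_cohort")
}
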