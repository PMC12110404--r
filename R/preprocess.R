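#' Tumor-centered cropping
#'
#' Crops a window centered on the segmentation-mask centroid (rounded to
#' the nearest pixel), padding with the image's minimum intensity where the
#' window exceeds the image bounds.  If the mask's bounding box exceeds the
#' window in either dimension the full bounding box is cropped instead --
#' the tumor boundary is preserved -- and the crop is resized back to
#' `window` x `window` by bilinear interpolation.  Coordinates are 0-based
#' row-major and crops are half-open intervals, so the output shape is
#' always exactly `window` x `window`.
#'
#' @param image 2-D intensity matrix.
#' @param mask logical (or 0/1) matrix of the same shape; must contain at
#'   least one foreground pixel.
#' @param window side length of the output crop, in pixels.
#' @return `window` x `window` numeric matrix.
#' @export
crop_to_tumor <- function(image, mask, window = 128L) {
  plan <- crop_plan(mask, window)
  apply_crop(image, plan, fill = min(image))
}

# Decide the crop geometry from the mask alone so image and mask can be
# cropped identically.
crop_plan <- function(mask, window) {
  mask <- mask > 0
  if (!any(mask)) {
    stop("unusable segmentation: mask has no foreground pixels", call. = FALSE)
  }
  window <- as.integer(window)
  idx <- which(mask, arr.ind = TRUE)
  bb_r <- range(idx[, 1]); bb_c <- range(idx[, 2])
  if (diff(bb_r) + 1L > window || diff(bb_c) + 1L > window) {
    # Tumor larger than the window: preserve the boundary, resize later.
    return(list(type = "bbox", rows = bb_r[1]:bb_r[2], cols = bb_c[1]:bb_c[2],
                window = window))
  }
  # 0-based centroid, rounded; half-open window [start, start + window)
  cr <- round(mean(idx[, 1]) - 1)
  cc <- round(mean(idx[, 2]) - 1)
  r0 <- cr - window %/% 2L
  c0 <- cc - window %/% 2L
  list(type = "window", rows = (r0 + 1L):(r0 + window),
       cols = (c0 + 1L):(c0 + window), window = window)
}

apply_crop <- function(image, plan, fill) {
  H <- nrow(image); W <- ncol(image)
  out <- matrix(fill, length(plan$rows), length(plan$cols))
  rin <- plan$rows >= 1L & plan$rows <= H
  cin <- plan$cols >= 1L & plan$cols <= W
  out[rin, cin] <- image[plan$rows[rin], plan$cols[cin]]
  if (plan$type == "bbox") {
    out <- resize_bilinear(out, plan$window, plan$window)
  }
  out
}

#' Augmentation configuration
#'
#' Controls the random augmentations applied to training slices, in the
#' order: rotation, crop-and-resize, horizontal flip, vertical flip,
#' brightness/contrast jitter.  All knobs at zero give the identity.
#'
#' @param rotation_degrees maximum absolute rotation, degrees; the angle is
#'   drawn uniformly from its +/- range.
#' @param crop_fraction maximum fraction of the side length removed by the
#'   random crop (the crop is resized back to the input size); in [0,1).
#' @param flip_horizontal,flip_vertical flip probabilities in [0,1].
#' @param jitter_brightness,jitter_contrast maximum relative brightness /
#'   contrast change; factors are drawn uniformly from 1 +/- the value.
#' @param seed optional integer seed used when the config is applied to a
#'   whole cohort.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(rotation_degrees = 10,
                           crop_fraction = 0.1,
                           flip_horizontal = 0.5,
                           flip_vertical = 0.5,
                           jitter_brightness = 0.1,
                           jitter_contrast = 0.1,
                           seed = NULL) {
  cfg <- list(rotation_degrees = rotation_degrees,
              crop_fraction = crop_fraction,
              flip_horizontal = flip_horizontal,
              flip_vertical = flip_vertical,
              jitter_brightness = jitter_brightness,
              jitter_contrast = jitter_contrast,
              seed = seed)
  probs <- c(cfg$flip_horizontal, cfg$flip_vertical)
  if (any(probs < 0 | probs > 1)) {
    stop("flip probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$crop_fraction < 0 || cfg$crop_fraction >= 1) {
    stop("crop_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$jitter_brightness < 0 || cfg$jitter_brightness >= 1 ||
      cfg$jitter_contrast < 0 || cfg$jitter_contrast >= 1) {
    stop("jitter fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "augment_config")
}

#' Apply random augmentation to one slice
#'
#' Uses the current RNG state; seed outside for reproducibility.  The
#' output is clipped to [0,1].  With all knobs zero the input is returned
#' unchanged (bit-identical).
#'
#' @param image intensity matrix in [0,1].
#' @param config an [augment_config()].
#' @return augmented matrix of the same shape.
#' @export
augment_image <- function(image, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  out <- image
  if (config$rotation_degrees > 0) {
    ang <- stats::runif(1, -config$rotation_degrees, config$rotation_degrees)
    out <- rotate_image(out, ang, fill = min(out))
  }
  if (config$crop_fraction > 0) {
    side <- nrow(out)
    keep <- 1 - stats::runif(1, 0, config$crop_fraction)
    cs <- max(2L, round(side * keep))
    r0 <- sample.int(side - cs + 1L, 1L)
    c0 <- sample.int(side - cs + 1L, 1L)
    out <- resize_bilinear(out[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)],
                           side, side)
  }
  if (config$flip_horizontal > 0 && stats::runif(1) < config$flip_horizontal) {
    out <- out[, rev(seq_len(ncol(out)))]
  }
  if (config$flip_vertical > 0 && stats::runif(1) < config$flip_vertical) {
    out <- out[rev(seq_len(nrow(out))), ]
  }
  if (config$jitter_brightness > 0) {
    b <- 1 + stats::runif(1, -config$jitter_brightness,
                          config$jitter_brightness)
    out <- out * b
  }
  if (config$jitter_contrast > 0) {
    cfac <- 1 + stats::runif(1, -config$jitter_contrast,
                             config$jitter_contrast)
    out <- (out - mean(out)) * cfac + mean(out)
  }
  if (!identical(out, image)) out <- clip01(out)
  out
}

# Rotate about the image center by `degrees` (counter-clockwise), bilinear
# inverse mapping, out-of-bounds pixels set to `fill`.
rotate_image <- function(image, degrees, fill = 0) {
  if (degrees == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  th <- degrees * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- matrix(rep(seq_len(H), W), H, W) - cr
  c <- matrix(rep(seq_len(W), each = H), H, W) - cc
  src_r <- cos(th) * r + sin(th) * c + cr
  src_c <- -sin(th) * r + cos(th) * c + cc
  bilinear_sample(image, src_r, src_c, fill)
}

# Sample an image at continuous (row, col) locations with bilinear weights.
bilinear_sample <- function(image, r, c, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  r <- as.numeric(r); c <- as.numeric(c)
  inside <- r >= 1 & r <= H & c >= 1 & c <= W
  r0 <- pmin(pmax(floor(r), 1), H - 1); c0 <- pmin(pmax(floor(c), 1), W - 1)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    fr * (1 - fc) * image[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * image[cbind(r0, c0 + 1)] +
    fr * fc * image[cbind(r0 + 1, c0 + 1)]
  v[!inside] <- fill
  matrix(v, H, W)
}

#' Equalize per-class slice counts by minority upsampling
#'
#' Minority-class slices are resampled with replacement until both classes
#' have equal slice counts.  All original samples are retained; duplicates
#' reuse the underlying image (later augmentation diversifies them) and get
#' a disambiguated slice id.
#'
#' @param cohort a `drlroi_cohort` (or plain list of samples).
#' @return object of the same type with balanced per-class slice counts.
#' @export
balance_upsample <- function(cohort) {
  samples <- if (inherits(cohort, "drlroi_cohort")) cohort$samples else cohort
  labels <- vapply(samples, `[[`, 0L, "label")
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) {
    stop("balance_upsample needs both classes present", call. = FALSE)
  }
  if (tab[1] != tab[2]) {
    minority <- as.integer(names(tab)[which.min(tab)])
    need <- abs(diff(as.integer(tab)))
    pool <- which(labels == minority)
    extra <- sample(pool, need, replace = TRUE)
    for (k in seq_along(extra)) {
      dup <- samples[[extra[k]]]
      dup$slice_id <- sprintf("%s_dup%02d", dup$slice_id, k)
      samples[[length(samples) + 1L]] <- dup
    }
  }
  if (inherits(cohort, "drlroi_cohort")) {
    cohort_from_samples(samples, cohort$config)
  } else {
    samples
  }
}

#' Patient-level hold-out split with balanced validation
#'
#' Randomly assigns whole patients to the training or validation cohort;
#' the validation cohort holds exactly `n_val_per_class` patients of each
#' class, so no slice of any patient appears on both sides.
#'
#' @param cohort a `drlroi_cohort`.
#' @param n_val_per_class validation patients per class.
#' @param seed integer seed making the assignment deterministic.
#' @return list with elements `train` and `val`, both `drlroi_cohort`.
#' @export
split_cohort <- function(cohort, n_val_per_class, seed = 1L) {
  man <- cohort_manifest(cohort)
  pat <- unique(man[, c("patient_id", "label")])
  val_ids <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(lb) {
      ids <- pat$patient_id[pat$label == lb]
      if (length(ids) <= n_val_per_class && n_val_per_class > 0) {
        stop("insufficient patients in class ", lb,
             " for a validation split of ", n_val_per_class, call. = FALSE)
      }
      if (n_val_per_class == 0) character(0) else sample(ids, n_val_per_class)
    }))
  })
  in_val <- vapply(cohort$samples,
                   function(s) s$patient_id %in% val_ids, TRUE)
  list(train = cohort_from_samples(cohort$samples[!in_val], cohort$config),
       val = cohort_from_samples(cohort$samples[in_val], cohort$config))
}

#' Crop every slice of a cohort to its tumor window
#'
#' Applies [crop_to_tumor()] to each slice; the mask is cropped with the
#' identical geometry (padded with background) so downstream localization
#' checks stay aligned with the image.
#'
#' @param cohort a `drlroi_cohort`.
#' @param window crop side length in pixels.
#' @return a `drlroi_cohort` whose images and masks are `window` square.
#' @export
preprocess_cohort <- function(cohort, window = 128L) {
  samples <- lapply(cohort$samples, function(s) {
    plan <- crop_plan(s$mask, window)
    s$image <- apply_crop(s$image, plan, fill = min(s$image))
    s$mask <- apply_crop(s$mask * 1.0, plan, fill = 0) > 0.5
    s
  })
  cohort_from_samples(samples, cohort$config)
}
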