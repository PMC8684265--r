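#' Specification of the two-class synthetic speckle phantom
#'
#' The generator emulates the one property the classifier needs from real
#' breast-ultrasound data: benign and malignant lesions differ in local
#' speckle texture (smooth versus coarse grain), not merely in brightness.
#' Fully developed speckle is synthesized as the squared magnitude of a
#' Gaussian-smoothed complex Gaussian field; the class controls the
#' smoothing (correlation) length. A central hypoechoic lesion with a
#' radius-perturbed boundary is carved out and its mask is emitted as the
#' ROI.
#'
#' @param image_side image side in pixels (square images).
#' @param n_per_class images generated per class.
#' @param benign_correlation_length speckle smoothing length (pixels) for
#'   the benign (smooth) class; must exceed the malignant one.
#' @param malignant_correlation_length smoothing length for the malignant
#'   (coarse) class.
#' @param lesion_contrast fractional intensity drop inside the lesion
#'   (hypoechoic core): interior intensities are scaled by
#'   \code{1 - lesion_contrast}.
#' @param boundary_irregularity radial perturbation amplitude of the lesion
#'   margin for the malignant class (0 = perfect disk); benign margins use
#'   one fifth of it, mirroring the smoother margins of benign lesions.
#' @param noise_floor standard deviation of additive Gaussian sensor noise.
#' @param class_mean_shift optional additive brightness offset given to the
#'   benign lesion interior ("easy mode" for fast tests); 0 by default so
#'   classes differ only in texture statistics.
#' @param train_fraction fraction of each class marked as training data in
#'   the manifest split column.
#' @param seed master seed; every image is deterministic given
#'   (seed, class, index).
#' @return a \code{synth_spec} list.
#' @export
synth_spec <- function(image_side = 128L, n_per_class = 100L,
                       benign_correlation_length = 3.0,
                       malignant_correlation_length = 1.2,
                       lesion_contrast = 0.45,
                       boundary_irregularity = 0.25,
                       noise_floor = 0.02,
                       class_mean_shift = 0,
                       train_fraction = 0.8,
                       seed = 1L) {
  if (image_side < 32) stop_lrsc("image_side must be at least 32 pixels")
  if (benign_correlation_length <= 0 || malignant_correlation_length <= 0) {
    stop_lrsc("correlation lengths must be positive")
  }
  if (benign_correlation_length <= malignant_correlation_length) {
    stop_lrsc("benign (smooth) class must have the larger correlation length")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_lrsc("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(
    image_side = as.integer(image_side), n_per_class = as.integer(n_per_class),
    benign_correlation_length = benign_correlation_length,
    malignant_correlation_length = malignant_correlation_length,
    lesion_contrast = lesion_contrast,
    boundary_irregularity = boundary_irregularity,
    noise_floor = noise_floor, class_mean_shift = class_mean_shift,
    train_fraction = train_fraction, seed = as.integer(seed)
  ), class = "synth_spec")
}

# stationary smoothing on the torus: gaussian kernel applied in Fourier space
smooth_field_fft <- function(Z, sigma) {
  S <- nrow(Z)
  d <- pmin(0:(S - 1), S - (0:(S - 1)))
  g <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  g <- g / sum(g)
  stats::fft(stats::fft(Z) * stats::fft(g), inverse = TRUE) / S^2
}

#' Generate one synthetic lesion image
#'
#' Deterministic given \code{(spec$seed, class, index)}: regenerating the
#' same triple yields a bit-identical image and mask.
#'
#' @param class \code{"benign"} or \code{"malignant"}.
#' @param spec a \code{\link{synth_spec}}.
#' @param index image index within the class (1-based).
#' @return a \code{gray_image} with the lesion mask attached as \code{roi}
#'   and \code{image_id} of the form \code{benign_007}.
#' @export
generate_image <- function(class, spec, index = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  class <- normalize_label(class)
  if (is.na(class)) stop_lrsc("generate_image needs an explicit class")
  S <- spec$image_side
  cl <- if (class == "benign") spec$benign_correlation_length else
    spec$malignant_correlation_length
  irr <- if (class == "benign") spec$boundary_irregularity / 5 else
    spec$boundary_irregularity
  seed <- derive_seed(spec$seed, match(class, LRSC_CLASSES), index)
  with_seed(seed, {
    # fully developed speckle: |smoothed circular complex Gaussian|^2
    Z <- matrix(complex(real = stats::rnorm(S^2),
                        imaginary = stats::rnorm(S^2)), S, S)
    I <- Mod(smooth_field_fft(Z, cl))^2
    I <- I / mean(I)
    I <- pmin(I / stats::quantile(I, 0.995)[[1]], 1)
    # lesion boundary: radius-perturbed closed curve around the center
    R0 <- S * (0.26 + 0.06 * stats::runif(1))
    amp <- stats::rnorm(5)
    phase <- stats::runif(5, 0, 2 * pi)
    ctr <- (S + 1) / 2
    dy <- matrix(seq_len(S) - ctr, S, S)
    dx <- t(dy)
    theta <- atan2(dy, dx)
    perturb <- 0
    for (j in 1:5) perturb <- perturb + amp[j] * cos((j + 1) * theta + phase[j])
    perturb <- pmax(pmin(irr * perturb / sqrt(5), 0.6), -0.6)
    mask <- sqrt(dx^2 + dy^2) <= R0 * (1 + perturb)
    I[mask] <- I[mask] * (1 - spec$lesion_contrast)
    if (class == "benign" && spec$class_mean_shift > 0) {
      I[mask] <- I[mask] + spec$class_mean_shift
    }
    noise <- matrix(stats::rnorm(S^2, sd = spec$noise_floor), S, S)
    I <- pmin(pmax(I + noise, 0), 1)
    gray_image(I, roi = mask, label = class,
               image_id = sprintf("%s_%03d", class, index))
  })
}

#' Generate a full synthetic dataset on disk
#'
#' Writes \code{n_per_class} 8-bit PNG images and masks per class plus a
#' manifest CSV (columns \code{image,label,mask,split}) consumable by
#' \code{\link{read_manifest}}. The split column marks a seeded stratified
#' train/test partition with \code{train_fraction} of each class in train.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_lrsc("cannot create directory '%s'", out_dir)
  rows <- list()
  for (class in LRSC_CLASSES) {
    n <- spec$n_per_class
    n_train <- round(spec$train_fraction * n)
    train_idx <- with_seed(derive_seed(spec$seed, 999, match(class, LRSC_CLASSES)),
                           sample.int(n, n_train))
    for (i in seq_len(n)) {
      img <- generate_image(class, spec, i)
      img_file <- sprintf("%s_%03d.png", class, i)
      mask_file <- sprintf("%s_%03d_mask.png", class, i)
      png::writePNG(img$pixels, file.path(out_dir, img_file))
      png::writePNG(img$roi * 1.0, file.path(out_dir, mask_file))
      rows[[length(rows) + 1]] <- data.frame(
        image = img_file, label = class, mask = mask_file,
        split = if (i %in% train_idx) "train" else "test",
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all images referenced by a manifest
#'
#' @param manifest a manifest data.frame from \code{\link{read_manifest}}
#'   (or a path to one).
#' @return list of \code{gray_image} objects in manifest order.
#' @export
load_manifest_images <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    load_image(manifest$image[i],
               mask_path = if (is.na(manifest$mask[i])) NULL else manifest$mask[i],
               label = manifest$label[i])
  })
}
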