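#' Load a grayscale lesion image (optionally with an ROI mask)
#'
#' Reads a PNG or TIFF raster, converts RGB input to single-channel luminance
#' (Rec. 709 weights), and rescales intensities to \code{[0, 1]} by the
#' format's maximum value. An optional mask image is binarized at
#' \code{> 0} and attached as the region of interest (ROI).
#'
#' @param path path to a PNG or TIFF image, 2-D grayscale or RGB.
#' @param mask_path optional path to a mask image of identical size; nonzero
#'   pixels mark the inside of the lesion ROI.
#' @param label optional class label, \code{"benign"} or \code{"malignant"}
#'   (case-insensitive). Required later for training images.
#' @param image_id identifier stored with the image; defaults to the file
#'   name without extension.
#' @return a \code{gray_image} object: list with \code{pixels} (numeric
#'   matrix in \code{[0,1]}), \code{height}, \code{width}, \code{image_id},
#'   \code{label} (or \code{NA}), and \code{roi} (logical matrix or
#'   \code{NULL}).
#' @export
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8), image_id = "demo")
#' dim(img$pixels)
load_image <- function(path, mask_path = NULL, label = NULL, image_id = NULL) {
  pixels <- read_raster(path)
  roi <- NULL
  if (!is.null(mask_path) && !is.na(mask_path) && nzchar(mask_path)) {
    m <- read_raster(mask_path)
    if (!identical(dim(m), dim(pixels))) {
      stop_lrsc("mask shape (%d x %d) does not match image shape (%d x %d) for '%s'",
                nrow(m), ncol(m), nrow(pixels), ncol(pixels), path)
    }
    roi <- m > 0
  }
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  gray_image(pixels, roi = roi, label = label, image_id = image_id)
}

#' Construct a gray_image from an intensity matrix
#'
#' @param pixels numeric matrix with values in \code{[0, 1]}.
#' @param roi optional logical matrix of identical shape.
#' @param label optional class label.
#' @param image_id identifier string.
#' @return a \code{gray_image} object.
#' @export
gray_image <- function(pixels, roi = NULL, label = NULL, image_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_lrsc("pixels must be a numeric matrix")
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1) {
    stop_lrsc("pixel intensities must be finite and within [0, 1]")
  }
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(pixels))) {
      stop_lrsc("roi shape (%d x %d) does not match pixels shape (%d x %d)",
                nrow(roi), ncol(roi), nrow(pixels), ncol(pixels))
    }
    roi <- roi > 0
  }
  structure(list(
    pixels = pixels,
    height = nrow(pixels),
    width = ncol(pixels),
    image_id = as.character(image_id),
    label = normalize_label(label),
    roi = roi
  ), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %s: %d x %d, label = %s, roi = %s\n",
              x$image_id, x$height, x$width,
              ifelse(is.na(x$label), "<none>", x$label),
              if (is.null(x$roi)) "none" else
                sprintf("%.1f%% inside", 100 * mean(x$roi))))
  invisible(x)
}

# Decode a PNG/TIFF file to a 2-D intensity matrix in [0,1].
# png::readPNG / tiff::readTIFF already divide by the format max value.
read_raster <- function(path) {
  if (!file.exists(path)) stop_lrsc("image file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_lrsc("unsupported image format '%s' for '%s' (PNG or TIFF expected)",
              ext, path)
  )
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      # Rec. 709 luminance; an alpha channel, if present, is ignored
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  pmin(pmax(arr, 0), 1)
}

#' Read a dataset manifest
#'
#' Parses a CSV manifest with header columns \code{image,label,mask} (an
#' optional \code{split} column with values \code{train}/\code{test} is kept
#' when present). Relative paths are resolved against the manifest's
#' directory. Labels are matched case-insensitively against
#' \code{benign}/\code{malignant}; anything else is rejected with the
#' offending row number.
#'
#' @param path path to the manifest CSV.
#' @return a data.frame with columns \code{image}, \code{label}, \code{mask}
#'   (\code{NA} when absent) and, if present in the file, \code{split};
#'   rows in file order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_lrsc("manifest not found: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("image", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_lrsc("manifest '%s' lacks required column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  }
  if (!"mask" %in% names(df)) df$mask <- ""
  labs <- tolower(trimws(df$label))
  bad <- which(!(labs %in% LRSC_CLASSES))
  if (length(bad) > 0) {
    stop_lrsc("manifest '%s' row %d: unknown label '%s'", path, bad[1],
              df$label[bad[1]])
  }
  base <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    p <- trimws(p)
    ifelse(p == "" | is.na(p), NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  out <- data.frame(
    image = resolve(df$image),
    label = labs,
    mask = resolve(df$mask),
    stringsAsFactors = FALSE
  )
  if ("split" %in% names(df)) out$split <- tolower(trimws(df$split))
  out
}
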