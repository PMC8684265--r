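#' Sliding-window patch extraction
#'
#' Slides an \code{m x m} window over the image at the given stride and
#' returns every in-bounds patch, in row-major order of the (0-based)
#' top-left origins. When the image carries an ROI mask, only patches whose
#' fraction of in-ROI pixels is at least \code{roi_min_frac} are kept. Each
#' patch inherits the image's class label and records its origin.
#'
#' @param image a \code{gray_image}.
#' @param m patch side in pixels.
#' @param stride step between consecutive origins, \code{>= 1}.
#' @param roi_min_frac minimum fraction of patch pixels inside the ROI for
#'   the patch to be kept (ignored when the image has no ROI).
#' @return a \code{patch_set}: list with \code{values} (matrix, one row per
#'   patch of length \code{m * m}, row-major pixel order within the patch),
#'   \code{origin} (integer matrix of 0-based \code{(row, col)} corners),
#'   \code{image_id}, \code{label}, and \code{m}. The set may be empty.
#' @export
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4))
#' extract_patches(img, m = 2, stride = 2)$origin
extract_patches <- function(image, m, stride = max(1L, m %/% 2L),
                            roi_min_frac = 0.5) {
  stopifnot(inherits(image, "gray_image"))
  m <- as.integer(m); stride <- as.integer(stride)
  H <- image$height; W <- image$width
  if (m > min(H, W)) {
    stop_lrsc("patch side m = %d exceeds image size %d x %d", m, H, W)
  }
  if (stride < 1) stop_lrsc("stride must be >= 1")
  r0 <- seq.int(0L, H - m, by = stride)   # 0-based origins
  c0 <- seq.int(0L, W - m, by = stride)
  # row-major order over origins: all columns for the first row, then next row
  origin <- cbind(row = rep(r0, each = length(c0)),
                  col = rep(c0, times = length(r0)))
  # linear indices of one patch anchored at (0,0), in row-major pixel order
  base <- as.vector(t(outer(seq_len(m), (seq_len(m) - 1L) * H, `+`)))
  starts <- origin[, "row"] + origin[, "col"] * H  # 0-based linear offsets
  idx <- outer(starts, base, `+`)                  # n_patch x m^2
  values <- matrix(image$pixels[idx], nrow = nrow(origin))
  if (!is.null(image$roi)) {
    frac <- rowMeans(matrix(as.numeric(image$roi)[idx], nrow = nrow(origin)))
    keep <- frac >= roi_min_frac
    values <- values[keep, , drop = FALSE]
    origin <- origin[keep, , drop = FALSE]
  }
  patch_set(values, origin, image_id = image$image_id, label = image$label,
            m = m)
}

#' Construct a patch_set
#'
#' @param values numeric matrix, one patch per row (length \code{m^2},
#'   row-major within the patch).
#' @param origin integer matrix of 0-based \code{(row, col)} origins, or
#'   \code{NULL} for synthetic patches.
#' @param image_id parent image id(s): length 1 or one per patch.
#' @param label class label(s): length 1 or one per patch; may be \code{NA}.
#' @param m patch side.
#' @return a \code{patch_set} object.
#' @export
patch_set <- function(values, origin = NULL, image_id = "image", label = NA,
                      m) {
  m <- as.integer(m)
  if (!is.matrix(values)) values <- matrix(values, ncol = m * m)
  if (ncol(values) != m * m) {
    stop_lrsc("patch values have %d pixels; expected m^2 = %d", ncol(values),
              m * m)
  }
  n <- nrow(values)
  if (is.null(origin)) {
    origin <- matrix(NA_integer_, n, 2, dimnames = list(NULL, c("row", "col")))
  }
  rec <- function(x) {
    x <- as.character(x)
    if (length(x) == 1) rep(x, n) else x
  }
  structure(list(
    values = values,
    origin = origin,
    image_id = rec(image_id),
    label = normalize_label(rec(label)),
    m = m
  ), class = "patch_set")
}

#' Number of patches in a patch_set
#' @param x a \code{patch_set}.
#' @return integer count.
#' @export
n_patches <- function(x) nrow(x$values)

#' @export
print.patch_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = LRSC_CLASSES), useNA = "ifany")
  cat(sprintf("<patch_set> %d patches of %d x %d (%s)\n", n_patches(x), x$m,
              x$m, paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Concatenate patch sets
#'
#' @param ... \code{patch_set} objects with identical patch side.
#' @return one combined \code{patch_set}, rows in argument order.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  m <- sets[[1]]$m
  for (s in sets) {
    if (!inherits(s, "patch_set")) stop_lrsc("all inputs must be patch_set")
    if (s$m != m) stop_lrsc("patch sides differ: %d vs %d", s$m, m)
  }
  patch_set(
    do.call(rbind, lapply(sets, `[[`, "values")),
    do.call(rbind, lapply(sets, `[[`, "origin")),
    image_id = unlist(lapply(sets, `[[`, "image_id")),
    label = unlist(lapply(sets, `[[`, "label")),
    m = m
  )
}

#' Subset a patch_set
#' @param x a \code{patch_set}.
#' @param i row index vector.
#' @param ... unused.
#' @return the subsetted \code{patch_set}.
#' @export
`[.patch_set` <- function(x, i, ...) {
  patch_set(x$values[i, , drop = FALSE], x$origin[i, , drop = FALSE],
            image_id = x$image_id[i], label = x$label[i], m = x$m)
}
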