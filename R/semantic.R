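#' @title Semantic code generation and the self-matching vote
#'
#' @description Each patch's similarity vector is condensed to one bit: the
#' mean similarity over the benign references is thresholded at 0.5, so bit
#' 1 reads "this patch looks benign". The image's bits form its semantic
#' code; the training-free self-matching layer averages the bits and calls
#' the image benign when the average exceeds 0.5.
#'
#' @name semantic
NULL

#' One semantic bit from a local similarity vector
#'
#' @param f_ls similarity vector with the benign block in positions
#'   1..\code{k_benign}; all elements in \code{[0, 1]}.
#' @param k_benign number of benign references (the block averaged).
#' @return list with \code{p} (mean benign-block similarity) and \code{B}
#'   (1 if \code{p >= 0.5}, else 0; 1 reads "patch looks benign").
#' @export
#' @examples
#' semantic_bit(c(0.9, 0.8, 0.7, 0.2), k_benign = 4)
semantic_bit <- function(f_ls, k_benign) {
  k_benign <- as.integer(k_benign)
  if (k_benign < 1) stop_lrsc("the benign reference block must be non-empty")
  if (length(f_ls) < k_benign) {
    stop_lrsc("similarity vector of length %d is shorter than k_benign = %d",
              length(f_ls), k_benign)
  }
  if (any(f_ls < 0 | f_ls > 1)) stop_lrsc("similarities must lie in [0, 1]")
  p <- mean(f_ls[seq_len(k_benign)])
  list(p = p, B = as.integer(p >= 0.5))
}

new_semantic_code <- function(bits, p, image_id = "image") {
  structure(list(bits = as.integer(bits), per_patch_p = as.numeric(p),
                 n = length(bits), image_id = image_id),
            class = "semantic_code")
}

#' @export
print.semantic_code <- function(x, ...) {
  shown <- paste(x$bits[seq_len(min(x$n, 40))], collapse = "")
  if (x$n > 40) shown <- paste0(shown, "...")
  cat(sprintf("<semantic_code> %s: n = %d, bits = %s\n", x$image_id, x$n, shown))
  invisible(x)
}

#' Semantic code of an image
#'
#' Extracts the image's patches, scores every patch against every reference
#' with the trained encoder, and binarizes the per-patch benign-block mean
#' into one bit per patch, in patch extraction order.
#'
#' @param image a \code{gray_image}.
#' @param refs a \code{reference_set}.
#' @param encoder a trained \code{lrsc_encoder}.
#' @param stride patch stride (default half the patch side).
#' @param roi_min_frac ROI gating threshold for patches (see
#'   \code{\link{extract_patches}}).
#' @return a \code{semantic_code}: \code{bits}, the retained real-valued
#'   \code{per_patch_p}, the code length \code{n}, and the image id.
#' @export
image_semantic_code <- function(image, refs, encoder,
                                stride = max(1L, refs$m %/% 2L),
                                roi_min_frac = 0.5) {
  ps <- extract_patches(image, m = refs$m, stride = stride,
                        roi_min_frac = roi_min_frac)
  if (n_patches(ps) == 0) {
    stop_lrsc(paste0("image '%s' yields no patches under the ROI gate; ",
                     "lower roi_min_frac or the stride"), image$image_id)
  }
  sims <- similarity_matrix(ps, refs, encoder)
  p <- rowMeans(sims[, seq_len(refs$k), drop = FALSE])
  new_semantic_code(as.integer(p >= 0.5), p, image_id = image$image_id)
}

#' Training-free self-matching classification
#'
#' Averages the semantic code's bits into \code{l} and labels the image
#' benign when \code{l} is strictly larger than 0.5, malignant otherwise
#' (the tie at exactly 0.5 goes to malignant). No parameters are learned or
#' stored.
#'
#' @param code a \code{semantic_code}, or a 0/1 bit vector.
#' @return list with \code{l} (mean bit) and \code{label}.
#' @export
#' @examples
#' self_match(c(1, 1, 0, 1))
self_match <- function(code) {
  bits <- if (inherits(code, "semantic_code")) code$bits else as.integer(code)
  if (length(bits) == 0) stop_lrsc("cannot classify an empty semantic code")
  if (any(!bits %in% c(0L, 1L))) stop_lrsc("semantic code bits must be 0 or 1")
  l <- mean(bits)
  list(l = l, label = if (l > 0.5) "benign" else "malignant")
}

#' Continuous benign-likelihood score of an image
#'
#' The mean of the per-patch benign-block similarities before
#' binarization. This finer-grained score is used only for ROC analysis;
#' the hard decision always comes from \code{\link{self_match}}.
#'
#' @inheritParams image_semantic_code
#' @return a real score in \code{[0, 1]}.
#' @export
continuous_score <- function(image, refs, encoder,
                             stride = max(1L, refs$m %/% 2L),
                             roi_min_frac = 0.5) {
  code <- image_semantic_code(image, refs, encoder, stride = stride,
                              roi_min_frac = roi_min_frac)
  code_score(code)
}

#' Score and decision from an already computed semantic code
#' @param code a \code{semantic_code}.
#' @return mean per-patch p (for \code{code_score}).
#' @export
code_score <- function(code) {
  stopifnot(inherits(code, "semantic_code"))
  mean(code$per_patch_p)
}

#' Export semantic codes as a data.frame / CSV
#'
#' @param codes list of \code{semantic_code} objects.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame with columns \code{image_id}, \code{n}, \code{bits}
#'   (0/1 string), \code{l}, \code{score}, \code{label}.
#' @export
codes_to_table <- function(codes, path = NULL) {
  rows <- lapply(codes, function(cd) {
    dec <- self_match(cd)
    data.frame(image_id = cd$image_id, n = cd$n,
               bits = paste(cd$bits, collapse = ""),
               l = dec$l, score = code_score(cd), label = dec$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
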