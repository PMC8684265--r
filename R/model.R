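#' Fit a local-reference semantic-code classifier
#'
#' The full training pipeline in one call: sliding-window patches are taken
#' from the ROI of every labeled training image; class-tagged local
#' references are learned by class-guided clustering; the tied-backbone
#' encoder with relation head is trained on balanced patch/reference pairs.
#' The returned object classifies new images through
#' \code{\link{predict.lrsc}} (semantic code + self-matching vote).
#'
#' @param x training data: a list of labeled \code{gray_image} objects, a
#'   manifest data.frame from \code{\link{read_manifest}}, or a manifest
#'   path. Every training image must carry a label.
#' @param k number of benign local references.
#' @param r number of malignant local references.
#' @param m patch side in pixels (>= 8).
#' @param stride patch stride; default half the side (50\% overlap).
#' @param roi_min_frac minimum in-ROI pixel fraction for a patch to count
#'   as a lesion patch.
#' @param max_iter clustering iteration cap.
#' @param config a \code{\link{train_config}} controlling encoder training.
#' @param seed master seed; clustering and training derive their own
#'   sub-seeds from it unless \code{config} overrides.
#' @return an object of class \code{lrsc}: list with \code{references},
#'   \code{encoder}, the patch settings, class counts, and the clustering /
#'   training metadata.
#' @seealso \code{\link{predict.lrsc}}, \code{\link{run_pipeline}}
#' @export
#' @examples
#' \donttest{
#' spec <- synth_spec(n_per_class = 6, image_side = 64)
#' imgs <- lapply(1:6, function(i)
#'   generate_image(if (i <= 3) "benign" else "malignant", spec, i))
#' fit <- lrsc(imgs, k = 2, r = 2,
#'             config = train_config(epochs = 1, pairs_per_epoch = 64))
#' predict(fit, imgs[[1]])
#' }
lrsc <- function(x, k = 25L, r = 25L, m = 16L,
                 stride = max(1L, m %/% 2L), roi_min_frac = 0.5,
                 max_iter = 300L, config = NULL, seed = 1L) {
  images <- as_image_list(x)
  labels <- vapply(images, `[[`, character(1), "label")
  if (any(is.na(labels))) stop_lrsc("every training image must be labeled")
  if (length(unique(labels)) < 2) {
    stop_lrsc("training data must contain both classes (found only '%s')",
              unique(labels))
  }
  if (is.null(config)) config <- train_config(seed = derive_seed(seed, 2))
  patches <- bind_patches(lapply(images, extract_patches, m = m,
                                 stride = stride,
                                 roi_min_frac = roi_min_frac))
  if (n_patches(patches) == 0) {
    stop_lrsc("no patches survived the ROI gate; lower roi_min_frac or stride")
  }
  refs <- learn_local_references(patches, k = k, r = r,
                                 seed = derive_seed(seed, 1),
                                 max_iter = max_iter)
  encoder <- train_encoder(patches, refs, config)
  structure(list(
    references = refs,
    encoder = encoder,
    m = as.integer(m), stride = as.integer(stride),
    roi_min_frac = roi_min_frac,
    seed = as.integer(seed),
    n_train_images = length(images),
    n_train_patches = n_patches(patches),
    class_counts = table(labels),
    call = match.call()
  ), class = "lrsc")
}

as_image_list <- function(x) {
  if (inherits(x, "gray_image")) return(list(x))
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "gray_image")) return(x)
  if (is.character(x) || is.data.frame(x)) return(load_manifest_images(x))
  stop_lrsc("cannot interpret input as images (gray_image list, manifest data.frame, or manifest path expected)")
}

#' @export
print.lrsc <- function(x, ...) {
  cat("Local-reference semantic-code classifier\n")
  cat(sprintf("  references: %d benign + %d malignant prototypes of %d x %d\n",
              x$references$k, x$references$r, x$m, x$m))
  cat(sprintf("  trained on %d images (%s), %d lesion patches (stride %d)\n",
              x$n_train_images,
              paste(sprintf("%s: %d", names(x$class_counts), x$class_counts),
                    collapse = ", "),
              x$n_train_patches, x$stride))
  h <- x$encoder$history
  if (nrow(h) > 0) {
    cat(sprintf("  encoder: %d epochs, final pair accuracy %.3f\n", nrow(h),
                h$accuracy[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.lrsc <- function(object, ...) {
  print(object)
  meta <- object$references$meta
  cat(sprintf("  clustering: %d iterations, objective %.5g, converged: %s\n",
              meta$iterations, meta$objective, meta$converged))
  cfg <- object$encoder$config
  if (!is.null(cfg)) {
    cat(sprintf("  optimizer: SGD lr %.4g, momentum %.2f, weight decay %.1g, batch %d, %d pairs/epoch\n",
                cfg$learning_rate, cfg$momentum, cfg$weight_decay,
                cfg$batch_size, cfg$pairs_per_epoch))
  }
  invisible(object)
}

#' Model parameters of a fitted classifier
#'
#' @param object an \code{lrsc} fit.
#' @param ... unused.
#' @return list with the reference arrays and the encoder parameter arrays.
#' @export
coef.lrsc <- function(object, ...) {
  list(benign_references = object$references$benign,
       malignant_references = object$references$malignant,
       backbone = object$encoder$backbone,
       head = object$encoder$head[c("W1", "b1", "W2", "b2", "W3", "b3")])
}

#' Classify new images with a fitted classifier
#'
#' Each image is encoded into its semantic code and classified by the
#' training-free self-matching vote.
#'
#' @param object an \code{lrsc} fit.
#' @param newdata a \code{gray_image}, list of them, manifest data.frame,
#'   or manifest path.
#' @param type \code{"table"} (default; one row per image with label,
#'   vote fraction l, continuous score and code length), \code{"class"}
#'   (label vector), \code{"score"} (numeric benign-likelihood vector), or
#'   \code{"code"} (list of \code{semantic_code} objects).
#' @param ... unused.
#' @return see \code{type}.
#' @export
predict.lrsc <- function(object, newdata,
                         type = c("table", "class", "score", "code"), ...) {
  type <- match.arg(type)
  images <- as_image_list(newdata)
  codes <- lapply(images, image_semantic_code, refs = object$references,
                  encoder = object$encoder, stride = object$stride,
                  roi_min_frac = object$roi_min_frac)
  if (type == "code") return(codes)
  tab <- codes_to_table(codes)
  tab$truth <- vapply(images, `[[`, character(1), "label")
  switch(type,
         table = tab,
         class = tab$label,
         score = tab$score)
}

#' Diagnostic plots of a fitted classifier
#'
#' Left: encoder training history (pair loss and pair accuracy). Right: the
#' learned local references as patch montages, benign row above malignant
#' row.
#'
#' @param x an \code{lrsc} fit.
#' @param max_refs maximum references per class to display.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.lrsc <- function(x, max_refs = 8L, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  nb <- min(x$references$k, max_refs)
  nm <- min(x$references$r, max_refs)
  nc <- max(nb, nm)
  lay <- rbind(rep(1L, nc),
               c(1L + seq_len(nb), rep(0L, nc - nb)),
               c(1L + nb + seq_len(nm), rep(0L, nc - nm)))
  graphics::layout(lay)
  h <- x$encoder$history
  graphics::par(mar = c(4, 4, 2, 1))
  if (nrow(h) > 0) {
    graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                   ylab = "pair cross-entropy", main = "encoder training")
    graphics::lines(h$epoch, h$accuracy, lty = 2, col = "grey40")
    graphics::legend("right", legend = c("loss", "pair accuracy"),
                     lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  } else {
    graphics::plot.new(); graphics::title("untrained encoder")
  }
  draw_ref <- function(v, m, main) {
    img <- t(matrix(v, m, m, byrow = TRUE))[, m:1]
    graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
    graphics::image(img, col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                    main = main, cex.main = 0.8)
  }
  for (i in seq_len(nb)) {
    draw_ref(x$references$benign[i, ], x$m, sprintf("benign %d", i))
  }
  for (i in seq_len(nm)) {
    draw_ref(x$references$malignant[i, ], x$m, sprintf("malignant %d", i))
  }
  invisible(x)
}
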