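#' @title Tied-parameter feature extractor and relation head
#'
#' @description Both the local patch and the local reference are mapped by
#' one and the same convolutional backbone (three 3x3/32-filter blocks with
#' batch normalization, ReLU and 2x2 max pooling, then global average
#' pooling to a 32-vector). The two features are combined by elementwise
#' absolute difference and passed through two ReLU fully connected layers
#' and a 2-unit softmax whose "related" probability is the learned
#' patch-to-reference similarity.
#'
#' @name encoder
NULL

#' Training configuration for the encoder
#'
#' Optimization is plain stochastic gradient descent with momentum; the
#' defaults for learning rate, momentum and weight decay are 0.001, 0.9 and
#' 1e-6.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to convolution and dense weights
#'   (not to biases or batch-norm parameters).
#' @param batch_size pairs per SGD step.
#' @param epochs training epochs; 0 returns the seeded initialization.
#' @param pairs_per_epoch patch/reference pairs sampled each epoch.
#' @param hidden widths of the two hidden layers of the relation head.
#' @param seed seed governing initialization and all pair sampling.
#' @return a \code{train_config} list.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 1e-6, batch_size = 64L,
                         epochs = 30L, pairs_per_epoch = 1024L,
                         hidden = c(64L, 64L), seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, weight_decay >= 0,
            batch_size >= 1, epochs >= 0, pairs_per_epoch >= 1,
            length(hidden) == 2)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pairs_per_epoch = as.integer(pairs_per_epoch),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "train_config")
}

# patch_set / matrix / single m x m patch -> (N, m, m, 1) array.
# Flattened rows are row-major within the patch.
as_patch_array <- function(x, m = NULL) {
  V <- if (inherits(x, "patch_set")) {
    m <- x$m; x$values
  } else if (is.matrix(x) && !is.null(m) && ncol(x) == m * m) {
    x
  } else if (is.matrix(x) && nrow(x) == ncol(x)) {
    m <- nrow(x); matrix(as.vector(t(x)), 1)
  } else if (is.numeric(x) && !is.null(m) && length(x) == m * m) {
    matrix(x, 1)
  } else {
    stop_lrsc("cannot interpret input as patches")
  }
  if (m < 8) stop_lrsc("patch side %d is below the minimum of 8 required by three pooling stages", m)
  B <- array(V, c(nrow(V), m, m))
  A <- aperm(B, c(1, 3, 2))  # rows were row-major; array fill is column-major
  dim(A) <- c(nrow(V), m, m, 1)
  A
}

ref_matrix <- function(refs) rbind(refs$benign, refs$malignant)

ref_labels <- function(refs) {
  c(rep("benign", refs$k), rep("malignant", refs$r))
}

#' Initialize an untrained encoder
#'
#' @param m patch side the encoder will consume.
#' @param hidden hidden-layer widths of the relation head.
#' @param seed seed for the parameter initialization.
#' @return an \code{lrsc_encoder}: backbone + head parameters with empty
#'   training history.
#' @export
init_encoder <- function(m, hidden = c(64L, 64L), seed = 1L) {
  with_seed(seed, {
    structure(list(
      backbone = init_backbone(32L),
      head = init_head(32L, hidden),
      m = as.integer(m),
      history = data.frame(epoch = integer(0), loss = numeric(0),
                           accuracy = numeric(0)),
      config = NULL
    ), class = "lrsc_encoder")
  })
}

#' @export
print.lrsc_encoder <- function(x, ...) {
  cat(sprintf("<lrsc_encoder> tied 3-block CNN backbone (32 features) + relation head (%s)\n",
              paste(x$head$hidden, collapse = "-")))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final pair loss %.4f, pair accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  } else {
    cat("  untrained (random initialization)\n")
  }
  invisible(x)
}

#' Backbone features of patches
#'
#' Runs inputs through the shared convolutional backbone. In \code{eval}
#' mode batch normalization uses the stored running statistics, so the
#' output is deterministic; \code{train} mode uses batch statistics and is
#' only meant for use inside the training loop.
#'
#' @param input a \code{patch_set}, an \code{m x m} matrix (single patch),
#'   or an \code{n x m^2} matrix of flattened patches.
#' @param encoder an \code{lrsc_encoder}.
#' @param mode \code{"eval"} (default) or \code{"train"}.
#' @return a numeric matrix, one row of 32 features per input patch (a
#'   single patch yields a 1 x 32 matrix).
#' @export
cnn_features <- function(input, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- as_patch_array(input, encoder$m)
  backbone_forward(encoder$backbone, X, train = (mode == "train"))$features
}

#' Combine two feature vectors by elementwise absolute difference
#'
#' @param a,b numeric vectors (or matrices, row-wise) of equal length.
#' @return \code{|a - b|}, the nonnegative combined feature.
#' @export
combine_features <- function(a, b) {
  if (length(a) != length(b)) {
    stop_lrsc("feature lengths differ: %d vs %d", length(a), length(b))
  }
  abs(a - b)
}

head_similarity <- function(encoder, V) {
  head_forward(encoder$head, V)$probs[, 2L]
}

#' Learned similarity between a patch and a reference
#'
#' Features of both inputs are taken from the shared backbone (eval mode),
#' combined by absolute difference, and scored by the relation head; the
#' returned value is the softmax probability of the "related" unit, in
#' \code{[0, 1]}. By construction it is symmetric in its two arguments.
#'
#' @param patch an \code{m x m} matrix or flattened patch vector.
#' @param reference an \code{m x m} matrix or flattened reference vector.
#' @param encoder a trained \code{lrsc_encoder}.
#' @return similarity in \code{[0, 1]}.
#' @export
similarity <- function(patch, reference, encoder) {
  fa <- cnn_features(patch, encoder)
  fb <- cnn_features(reference, encoder)
  unname(head_similarity(encoder, abs(fa - fb)))
}

# similarity of every patch row to every reference row; returns a
# n_patches x (k + r) matrix, benign references in columns 1..k.
similarity_matrix <- function(patches, refs, encoder, chunk = 512L) {
  V <- if (inherits(patches, "patch_set")) patches$values else patches
  R <- ref_matrix(refs)
  Fr <- cnn_features(R, encoder)
  n <- nrow(V); nref <- nrow(R)
  out <- matrix(NA_real_, n, nref)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    Fp <- cnn_features(V[rows, , drop = FALSE], encoder)
    # all patch x reference combinations in one head pass
    big <- abs(Fp[rep(seq_along(rows), each = nref), , drop = FALSE] -
                 Fr[rep(seq_len(nref), times = length(rows)), , drop = FALSE])
    out[rows, ] <- matrix(head_similarity(encoder, big), nrow = length(rows),
                          byrow = TRUE)
  }
  out
}

#' Local similarity feature of a patch
#'
#' The vector of learned similarities between one patch and every local
#' reference; its length is the number of references, with the k benign
#' references in positions 1..k followed by the r malignant references.
#'
#' @param patch an \code{m x m} matrix or flattened patch vector.
#' @param refs a \code{reference_set}.
#' @param encoder a trained \code{lrsc_encoder}.
#' @return numeric vector of length \code{k + r}, each element in
#'   \code{[0, 1]}.
#' @export
local_similarity_feature <- function(patch, refs, encoder) {
  V <- if (is.matrix(patch) && nrow(patch) == ncol(patch)) {
    matrix(as.vector(t(patch)), 1)
  } else {
    matrix(patch, 1)
  }
  as.vector(similarity_matrix(V, refs, encoder))
}

#' Sample balanced patch/reference training pairs
#'
#' Draws \code{n_pairs} (patch, reference) pairs with an even split of
#' relation labels: label 1 pairs a patch with a same-class reference,
#' label 0 with an opposite-class reference.
#'
#' @param patches a labeled \code{patch_set} containing both classes.
#' @param refs a \code{reference_set}.
#' @param n_pairs number of pairs.
#' @param seed sampling seed.
#' @return data.frame with columns \code{patch} (row in \code{patches}),
#'   \code{reference} (row in the benign-first reference stack) and
#'   \code{label} (0/1), in randomized order.
#' @export
make_pairs <- function(patches, refs, n_pairs, seed = 1L) {
  idx <- split_by_class(patches)
  if (length(idx$benign) == 0 || length(idx$malignant) == 0) {
    stop_lrsc("pair sampling needs patches from both classes (benign: %d, malignant: %d)",
              length(idx$benign), length(idx$malignant))
  }
  rlab <- ref_labels(refs)
  with_seed(seed, {
    n_pos <- ceiling(n_pairs / 2)
    n_neg <- n_pairs - n_pos
    draw <- function(n, related) {
      if (n == 0) {
        return(data.frame(patch = integer(0), reference = integer(0),
                          label = integer(0)))
      }
      cls <- sample(LRSC_CLASSES, n, replace = TRUE)
      pi <- ifelse(cls == "benign",
                   idx$benign[sample.int(length(idx$benign), n, replace = TRUE)],
                   idx$malignant[sample.int(length(idx$malignant), n, replace = TRUE)])
      want <- if (related) cls else ifelse(cls == "benign", "malignant", "benign")
      ri <- vapply(want, function(w) {
        pool <- which(rlab == w)
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      data.frame(patch = pi, reference = unname(ri),
                 label = as.integer(related))
    }
    out <- rbind(draw(n_pos, TRUE), draw(n_neg, FALSE))
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Train the encoder on patch/reference relation pairs
#'
#' Minimizes the 2-way cross-entropy of the relation output over freshly
#' sampled balanced pairs each epoch, by SGD with momentum and weight decay
#' as set in \code{config}. References are frozen; only backbone and head
#' parameters move. Fully seeded: identical inputs and config give an
#' identical encoder.
#'
#' @param patches a labeled \code{patch_set} with at least 2 patches per
#'   class.
#' @param refs the learned \code{reference_set} (frozen during training).
#' @param config a \code{\link{train_config}}.
#' @return a trained \code{lrsc_encoder}; \code{$history} holds one row per
#'   epoch with the mean pair loss and pair accuracy.
#' @export
train_encoder <- function(patches, refs, config = train_config()) {
  idx <- split_by_class(patches)
  if (length(idx$benign) < 2 || length(idx$malignant) < 2) {
    stop_lrsc("training needs >= 2 patches per class (benign: %d, malignant: %d)",
              length(idx$benign), length(idx$malignant))
  }
  check_sides(patches, refs)
  enc <- init_encoder(patches$m, hidden = config$hidden, seed = config$seed)
  enc$config <- config
  if (config$epochs == 0) return(enc)
  R <- ref_matrix(refs)
  vel <- zero_like_params(enc)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    pairs <- make_pairs(patches, refs, config$pairs_per_epoch,
                        seed = derive_seed(config$seed, 1000 + epoch))
    nb <- nrow(pairs)
    loss_sum <- 0; acc_sum <- 0
    starts <- seq(1L, nb, by = config$batch_size)
    for (bi in seq_along(starts)) {
      rows <- starts[bi]:min(starts[bi] + config$batch_size - 1L, nb)
      batch <- pairs[rows, , drop = FALSE]
      step <- encoder_sgd_step(enc, vel, patches, R, batch, config)
      enc <- step$enc; vel <- step$vel
      if (!is.finite(step$loss)) {
        stop_lrsc("non-finite loss at epoch %d, batch %d", epoch, bi)
      }
      loss_sum <- loss_sum + step$loss * nrow(batch)
      acc_sum <- acc_sum + step$correct
    }
    history$loss[epoch] <- loss_sum / nb
    history$accuracy[epoch] <- acc_sum / nb
  }
  enc$history <- history
  enc
}

zero_like_params <- function(enc) {
  zl <- function(x) array(0, dim(x) %||% length(x))
  list(
    blocks = lapply(enc$backbone$blocks, function(bl) {
      list(W = zl(bl$W), b = zl(bl$b), gamma = zl(bl$gamma), beta = zl(bl$beta))
    }),
    head = list(W1 = zl(enc$head$W1), b1 = zl(enc$head$b1),
                W2 = zl(enc$head$W2), b2 = zl(enc$head$b2),
                W3 = zl(enc$head$W3), b3 = zl(enc$head$b3))
  )
}

# one SGD step over a batch of pairs; returns updated encoder + velocities
encoder_sgd_step <- function(enc, vel, patches, R, batch, config) {
  upatch <- sort(unique(batch$patch))
  uref <- sort(unique(batch$reference))
  p_rows <- match(batch$patch, upatch)
  r_rows <- length(upatch) + match(batch$reference, uref)
  X <- as_patch_array(rbind(patches$values[upatch, , drop = FALSE],
                            R[uref, , drop = FALSE]), patches$m)
  fwd <- backbone_forward(enc$backbone, X, train = TRUE)
  enc$backbone <- fwd$params  # running BN statistics advanced
  Fe <- fwd$features
  Vc <- abs(Fe[p_rows, , drop = FALSE] - Fe[r_rows, , drop = FALSE])
  hf <- head_forward(enc$head, Vc)
  n <- nrow(batch)
  target <- batch$label + 1L  # column 1: unrelated, column 2: related
  picked <- hf$probs[cbind(seq_len(n), target)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  correct <- sum((hf$probs[, 2] >= 0.5) == (batch$label == 1L))
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), target)] <- 1
  dLogits <- (hf$probs - Y) / n
  hb <- head_backward(enc$head, hf, dLogits)
  sgn <- sign(Fe[p_rows, , drop = FALSE] - Fe[r_rows, , drop = FALSE])
  dFp <- hb$dV * sgn
  agg <- rowsum(rbind(dFp, -dFp), group = c(p_rows, r_rows))
  dFeat <- matrix(0, nrow(Fe), ncol(Fe))
  dFeat[as.integer(rownames(agg)), ] <- agg
  bg <- backbone_backward(enc$backbone, fwd, dFeat)
  lr <- config$learning_rate; mo <- config$momentum; wd <- config$weight_decay
  upd <- function(value, grad, v, decay) {
    v <- mo * v - lr * (grad + decay * value)
    list(value = value + v, v = v)
  }
  for (i in 1:3) {
    bl <- enc$backbone$blocks[[i]]; g <- bg[[i]]; vv <- vel$blocks[[i]]
    s <- upd(bl$W, g$dW, vv$W, wd); bl$W <- s$value; vv$W <- s$v
    s <- upd(bl$b, g$db, vv$b, 0); bl$b <- s$value; vv$b <- s$v
    s <- upd(bl$gamma, g$dgamma, vv$gamma, 0); bl$gamma <- s$value; vv$gamma <- s$v
    s <- upd(bl$beta, g$dbeta, vv$beta, 0); bl$beta <- s$value; vv$beta <- s$v
    enc$backbone$blocks[[i]] <- bl; vel$blocks[[i]] <- vv
  }
  for (nm in c("W1", "W2", "W3")) {
    s <- upd(enc$head[[nm]], hb[[paste0("d", nm)]], vel$head[[nm]], wd)
    enc$head[[nm]] <- s$value; vel$head[[nm]] <- s$v
  }
  for (nm in c("b1", "b2", "b3")) {
    s <- upd(enc$head[[nm]], hb[[paste0("d", nm)]], vel$head[[nm]], 0)
    enc$head[[nm]] <- s$value; vel$head[[nm]] <- s$v
  }
  list(enc = enc, vel = vel, loss = loss, correct = correct)
}

# ---- serialization ---------------------------------------------------------

pack_array <- function(x) list(dim = dim(x) %||% length(x), data = as.vector(x))
unpack_array <- function(p) {
  x <- as.numeric(unlist(p$data))
  d <- as.integer(unlist(p$dim))
  if (length(d) > 1) dim(x) <- d
  x
}

#' Save a trained encoder as JSON
#'
#' All parameter arrays (with dimensions) plus metadata are written to a
#' single plain-text JSON file, loadable for inference without the
#' training data.
#'
#' @param encoder an \code{lrsc_encoder}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_encoder <- function(encoder, path) {
  pk <- function(lst) lapply(lst, function(x) {
    if (is.numeric(x)) pack_array(x) else x
  })
  obj <- list(
    m = encoder$m,
    hidden = encoder$head$hidden,
    blocks = lapply(encoder$backbone$blocks, function(bl) {
      c(pk(bl[c("W", "b", "gamma", "beta")]),
        list(running_mean = pack_array(bl$running$mean),
             running_var = pack_array(bl$running$var)))
    }),
    head = pk(encoder$head[c("W1", "b1", "W2", "b2", "W3", "b3")]),
    config = unclass(encoder$config),
    history = encoder$history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an encoder saved by \code{save_encoder}
#' @param path JSON file written by \code{\link{save_encoder}}.
#' @return an \code{lrsc_encoder}.
#' @export
load_encoder <- function(path) {
  obj <- jsonlite::read_json(path)
  blocks <- lapply(obj$blocks, function(bl) {
    list(W = unpack_array(bl$W), b = unpack_array(bl$b),
         gamma = unpack_array(bl$gamma), beta = unpack_array(bl$beta),
         running = list(mean = unpack_array(bl$running_mean),
                        var = unpack_array(bl$running_var)))
  })
  head <- lapply(obj$head, unpack_array)
  head$hidden <- as.integer(unlist(obj$hidden))
  history <- if (length(obj$history) == 0) {
    data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  } else {
    do.call(rbind, lapply(obj$history, function(row) {
      data.frame(epoch = as.integer(row$epoch), loss = as.numeric(row$loss),
                 accuracy = as.numeric(row$accuracy))
    }))
  }
  cfg <- obj$config
  structure(list(
    backbone = structure(list(blocks = blocks, channels = 32L),
                         class = "backbone_params"),
    head = structure(head, class = "head_params"),
    m = as.integer(obj$m),
    history = history,
    config = if (is.null(cfg)) NULL else
      do.call(train_config, lapply(cfg, unlist))
  ), class = "lrsc_encoder")
}
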