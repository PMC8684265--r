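#' @title Class-tagged local references (prototype patches)
#'
#' @description Local references are the learned codebook of common local
#' tumor structures: \code{k} benign prototypes and \code{r} malignant
#' prototypes, each an \code{m x m} intensity patch. They are fit by
#' minimizing a class-guided sum of squared Euclidean distances between each
#' labeled patch and its nearest same-class reference; the class-indicator
#' weighting makes the benign and malignant terms independent, so the fit is
#' two Lloyd-style clusterings whose centroids keep their class tags.
#'
#' @name local_references
NULL

new_reference_set <- function(benign, malignant, m, meta = list()) {
  structure(list(
    benign = benign,       # k x m^2 matrix
    malignant = malignant, # r x m^2 matrix
    m = as.integer(m),
    k = nrow(benign),
    r = nrow(malignant),
    meta = meta
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d benign + %d malignant references of %d x %d",
              x$k, x$r, x$m, x$m))
  if (!is.null(x$meta$iterations)) {
    cat(sprintf(" (converged in %d iterations, objective %.6g)",
                x$meta$iterations, x$meta$objective))
  }
  cat("\n")
  invisible(x)
}

split_by_class <- function(patches) {
  lab <- patches$label
  if (any(is.na(lab))) stop_lrsc("all patches must carry a class label")
  list(benign = which(lab == "benign"), malignant = which(lab == "malignant"))
}

#' Randomly initialize local references from labeled patches
#'
#' Samples \code{k} distinct benign patches and \code{r} distinct malignant
#' patches without replacement under the seed and copies them as the initial
#' references.
#'
#' @param patches a labeled \code{patch_set}.
#' @param k number of benign references.
#' @param r number of malignant references.
#' @param seed integer seed; the same seed always yields the same
#'   initialization.
#' @return a \code{reference_set}.
#' @export
init_references <- function(patches, k, r, seed = 1L) {
  idx <- split_by_class(patches)
  nb <- length(idx$benign); nm <- length(idx$malignant)
  if (k > nb) stop_lrsc("k = %d exceeds the %d available benign patches", k, nb)
  if (r > nm) stop_lrsc("r = %d exceeds the %d available malignant patches", r, nm)
  if (k < 1 || r < 1) stop_lrsc("k and r must both be >= 1")
  with_seed(seed, {
    bi <- idx$benign[sample.int(nb, k)]
    mi <- idx$malignant[sample.int(nm, r)]
    new_reference_set(patches$values[bi, , drop = FALSE],
                      patches$values[mi, , drop = FALSE],
                      m = patches$m, meta = list(seed = as.integer(seed)))
  })
}

# squared Euclidean distances between rows of P (n x d) and rows of C (k x d)
sqdist <- function(P, C) {
  d2 <- outer(rowSums(P^2), rowSums(C^2), `+`) - 2 * tcrossprod(P, C)
  pmax(d2, 0)
}

#' Assign each patch to its nearest same-class reference
#'
#' Uses squared Euclidean distance on flattened raw intensities. Assignment
#' never crosses classes; ties go to the lowest reference index.
#'
#' @param patches a labeled \code{patch_set}.
#' @param refs a \code{reference_set} with matching patch side.
#' @return a \code{cluster_assignment}: list with integer vectors
#'   \code{benign} and \code{malignant} mapping each class's patches (in
#'   patch-set order) to a reference index, plus the index vectors
#'   \code{benign_idx}/\code{malignant_idx} locating those patches in the
#'   original set.
#' @export
assign_patches <- function(patches, refs) {
  check_sides(patches, refs)
  idx <- split_by_class(patches)
  assign_one <- function(rows, C) {
    if (length(rows) == 0) return(integer(0))
    d2 <- sqdist(patches$values[rows, , drop = FALSE], C)
    max.col(-d2, ties.method = "first")
  }
  structure(list(
    benign = assign_one(idx$benign, refs$benign),
    malignant = assign_one(idx$malignant, refs$malignant),
    benign_idx = idx$benign,
    malignant_idx = idx$malignant
  ), class = "cluster_assignment")
}

check_sides <- function(patches, refs) {
  if (patches$m != refs$m) {
    stop_lrsc("patch side %d does not match reference side %d", patches$m,
              refs$m)
  }
}

#' Recompute references as within-cluster means
#'
#' Each reference becomes the elementwise mean of the patches assigned to
#' it. A reference whose cluster is empty is repaired by replacing it with
#' the same-class patch lying farthest from its nearest current reference,
#' so no reference is ever NaN.
#'
#' @param patches a labeled \code{patch_set}.
#' @param assignment result of \code{\link{assign_patches}} against
#'   \code{refs}.
#' @param refs the \code{reference_set} the assignment was computed against.
#' @return an updated \code{reference_set}.
#' @export
update_references <- function(patches, assignment, refs) {
  upd <- function(rows, assign, C) {
    kk <- nrow(C)
    if (length(rows) == 0) return(C)
    P <- patches$values[rows, , drop = FALSE]
    counts <- tabulate(assign, nbins = kk)
    sums <- rowsum(P, group = assign)  # one row per non-empty cluster
    present <- as.integer(rownames(sums))
    newC <- C
    newC[present, ] <- sums / counts[present]
    empties <- which(counts == 0)
    if (length(empties) > 0) {
      # farthest-patch repair: outlying patches seed the dead references
      dmin <- apply(sqdist(P, newC[present, , drop = FALSE]), 1, min)
      ord <- order(dmin, decreasing = TRUE)
      take <- ord[seq_along(empties)]
      newC[empties, ] <- P[take, , drop = FALSE]
    }
    newC
  }
  new_reference_set(
    upd(assignment$benign_idx, assignment$benign, refs$benign),
    upd(assignment$malignant_idx, assignment$malignant, refs$malignant),
    m = refs$m, meta = refs$meta
  )
}

#' Class-guided clustering objective
#'
#' The sum over both classes of squared Euclidean distances between each
#' patch and its assigned same-class reference. The class indicators zero
#' out all cross-class terms, so only within-class distances contribute.
#'
#' @inheritParams update_references
#' @return a nonnegative number.
#' @export
objective_value <- function(patches, refs, assignment) {
  part <- function(rows, assign, C) {
    if (length(rows) == 0) return(0)
    P <- patches$values[rows, , drop = FALSE]
    sum((P - C[assign, , drop = FALSE])^2)
  }
  part(assignment$benign_idx, assignment$benign, refs$benign) +
    part(assignment$malignant_idx, assignment$malignant, refs$malignant)
}

#' Learn class-tagged local references by alternating optimization
#'
#' Alternates nearest-reference assignment and within-cluster mean updates
#' from a seeded random initialization until the assignment no longer
#' changes between consecutive iterations (or \code{max_iter} is reached).
#' The objective is non-increasing across iterations (the Lloyd property).
#'
#' @inheritParams init_references
#' @param max_iter iteration cap.
#' @return a converged \code{reference_set}; \code{$meta} records the seed,
#'   iteration count, final objective, and whether the assignment converged.
#' @export
#' @examples
#' ps <- patch_set(matrix(c(0, 0.1, 0.9, 1, 0.4, 0.6), ncol = 1),
#'                 label = c(rep("benign", 4), rep("malignant", 2)), m = 1)
#' refs <- learn_local_references(ps, k = 2, r = 1, seed = 7)
#' sort(refs$benign)
learn_local_references <- function(patches, k, r, seed = 1L, max_iter = 300L) {
  refs <- init_references(patches, k, r, seed)
  iter <- 0L
  converged <- FALSE
  assignment <- assign_patches(patches, refs)
  repeat {
    iter <- iter + 1L
    refs <- update_references(patches, assignment, refs)
    nxt <- assign_patches(patches, refs)
    same <- identical(assignment$benign, nxt$benign) &&
      identical(assignment$malignant, nxt$malignant)
    assignment <- nxt
    if (same) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  refs$meta <- list(seed = as.integer(seed), iterations = iter,
                    objective = objective_value(patches, refs, assignment),
                    converged = converged)
  refs
}

#' Persist a reference set as plain text
#'
#' Writes the two reference arrays as CSV (one reference per row, flattened
#' \code{m^2} pixels) plus a JSON sidecar with \code{m}, \code{k}, \code{r}
#' and the run metadata.
#'
#' @param refs a \code{reference_set}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(refs$benign, file.path(dir, "references_benign.csv"),
                   row.names = FALSE)
  utils::write.csv(refs$malignant, file.path(dir, "references_malignant.csv"),
                   row.names = FALSE)
  meta <- c(list(m = refs$m, k = refs$k, r = refs$r), refs$meta)
  jsonlite::write_json(meta, file.path(dir, "references_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a reference set saved by \code{save_references}
#' @param dir directory written by \code{\link{save_references}}.
#' @return a \code{reference_set}.
#' @export
load_references <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "references_meta.json"),
                              simplifyVector = TRUE)
  b <- as.matrix(utils::read.csv(file.path(dir, "references_benign.csv")))
  m <- as.matrix(utils::read.csv(file.path(dir, "references_malignant.csv")))
  dimnames(b) <- NULL; dimnames(m) <- NULL
  new_reference_set(b, m, m = meta$m,
                    meta = meta[setdiff(names(meta), c("m", "k", "r"))])
}
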