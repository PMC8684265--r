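# shared fixtures and independent oracles, all built in code at test time

# labeled one-pixel patch set from two numeric vectors
pixel_patches <- function(benign, malignant) {
  patch_set(matrix(c(benign, malignant), ncol = 1),
            label = rep(c("benign", "malignant"),
                        c(length(benign), length(malignant))),
            m = 1)
}

# random labeled patch set of side m
random_patches <- function(n_benign, n_malignant, m, seed = 1) {
  withr::with_seed(seed, {
    patch_set(matrix(runif((n_benign + n_malignant) * m * m),
                     n_benign + n_malignant, m * m),
              label = rep(c("benign", "malignant"), c(n_benign, n_malignant)),
              m = m)
  })
}

# ---- independent oracles ---------------------------------------------------

# exhaustive global minimum of the within-class k-means objective for one
# class: all k^n assignments, centroids = cluster means
enum_min_objective <- function(values, k) {
  n <- nrow(values)
  stopifnot(k^n <= 4e5)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    obj <- 0
    for (j in unique(assign)) {
      rows <- values[assign == j, , drop = FALSE]
      ctr <- colMeans(rows)
      obj <- obj + sum(sweep(rows, 2, ctr)^2)
    }
    if (obj < best) best <- obj
    # next assignment in base-k counting
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# brute-force pairwise AUC: fraction of benign/malignant pairs ordered
# correctly, half credit on ties
brute_auc <- function(scores, truth) {
  b <- scores[truth == "benign"]
  m <- scores[truth == "malignant"]
  tot <- 0
  for (x in b) for (y in m) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(b) * length(m))
}

# brute-force class-guided objective by explicit double loops
brute_objective <- function(patches, refs, assignment) {
  tot <- 0
  bi <- assignment$benign_idx
  for (t in seq_along(bi)) {
    tot <- tot + sum((patches$values[bi[t], ] -
                        refs$benign[assignment$benign[t], ])^2)
  }
  mi <- assignment$malignant_idx
  for (t in seq_along(mi)) {
    tot <- tot + sum((patches$values[mi[t], ] -
                        refs$malignant[assignment$malignant[t], ])^2)
  }
  tot
}

# small synthetic dataset on disk, cached for the test session
small_dataset <- local({
  cache <- new.env()
  function(n_per_class = 10, seed = 7) {
    key <- paste0("d", n_per_class, "_", seed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("lrsc_fix_", key))
      spec <- synth_spec(n_per_class = n_per_class, seed = seed)
      man <- generate_dataset(spec, dir)
      cache[[key]] <- man
    }
    cache[[key]]
  }
})

# a quickly trained small model shared across tests
quick_fit <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$fit)) {
      man <- read_manifest(small_dataset())
      train <- man[man$split == "train", ]
      cache$fit <- lrsc(train, k = 4, r = 4,
                        config = train_config(epochs = 2,
                                              pairs_per_epoch = 256,
                                              seed = 5),
                        seed = 5)
    }
    cache$fit
  }
})
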