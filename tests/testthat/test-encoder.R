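test_that("backbone emits 32 features for any input side >= 8", {
  enc16 <- init_encoder(16, seed = 1)
  p16 <- matrix(runif(256), 16, 16)
  expect_equal(dim(cnn_features(p16, enc16)), c(1, 32))
  enc9 <- init_encoder(9, seed = 1)
  expect_equal(dim(cnn_features(matrix(runif(81), 9, 9), enc9)), c(1, 32))
  enc7 <- init_encoder(7, seed = 1)
  expect_error(cnn_features(matrix(runif(49), 7, 7), enc7), "below the minimum")
})

test_that("tied parameters make both pipelines the same function", {
  enc <- init_encoder(16, seed = 2)
  p <- matrix(runif(256), 16, 16)
  # "patch pipeline" and "reference pipeline" are literally one call path
  expect_identical(cnn_features(p, enc), cnn_features(p, enc))
  # perturbing the single backbone perturbs both sides identically
  enc$backbone$blocks[[1]]$W[1, 1, 1, 1] <-
    enc$backbone$blocks[[1]]$W[1, 1, 1, 1] + 0.1
  f1 <- cnn_features(p, enc)
  f2 <- cnn_features(p, enc)
  expect_identical(f1, f2)
})

test_that("all-zero input maps to the zero feature at initialization", {
  enc <- init_encoder(16, seed = 3)
  # conv biases start at 0 and batch norm starts as the identity transform
  f <- cnn_features(matrix(0, 16, 16), enc)
  expect_equal(as.vector(f), rep(0, 32))
})

test_that("combine_features is the elementwise absolute difference", {
  expect_equal(combine_features(c(0.2, 0.5), c(0.7, 0.1)), c(0.5, 0.4))
  expect_equal(combine_features(1:4, 1:4), rep(0, 4))
  withr::with_seed(1, {
    a <- rnorm(32); b <- rnorm(32)
    expect_equal(combine_features(a, b), combine_features(b, a))
  })
  expect_error(combine_features(1:3, 1:4), "lengths differ")
})

test_that("zero-initialized final layer gives similarity exactly 0.5", {
  enc <- init_encoder(16, seed = 4)
  enc$head$W3[] <- 0
  enc$head$b3[] <- 0
  withr::with_seed(5, {
    for (i in 1:5) {
      s <- similarity(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16),
                      enc)
      expect_identical(s, 0.5)
    }
  })
})

test_that("similarity is symmetric and bounded on random draws", {
  withr::with_seed(6, {
    for (i in 1:5) {
      enc <- init_encoder(16, seed = 100 + i)
      p <- matrix(runif(256), 16, 16)
      q <- matrix(runif(256), 16, 16)
      s1 <- similarity(p, q, enc)
      s2 <- similarity(q, p, enc)
      expect_equal(s1, s2, tolerance = 1e-12)
      expect_gte(s1, 0); expect_lte(s1, 1)
    }
  })
})

test_that("local similarity feature has length k + r and matches per-pair calls", {
  ps <- random_patches(6, 5, 16, seed = 7)
  refs <- learn_local_references(ps, k = 3, r = 2, seed = 7)
  enc <- init_encoder(16, seed = 7)
  p <- ps$values[1, ]
  fls <- local_similarity_feature(p, refs, enc)
  expect_length(fls, 5)
  expect_true(all(fls >= 0 & fls <= 1))
  # element i equals an independently recomputed pairwise similarity
  R <- rbind(refs$benign, refs$malignant)
  for (i in c(1, 3, 5)) {
    ref_patch <- matrix(R[i, ], refs$m, refs$m, byrow = TRUE)
    expect_equal(fls[i], similarity(p, ref_patch, enc), tolerance = 1e-10)
  }
  # zeroed final layer -> every element 0.5
  enc$head$W3[] <- 0; enc$head$b3[] <- 0
  expect_equal(local_similarity_feature(p, refs, enc), rep(0.5, 5))
})

test_that("pair sampling is balanced, label-correct and seeded", {
  ps <- random_patches(8, 8, 8, seed = 8)
  refs <- learn_local_references(ps, k = 2, r = 2, seed = 8)
  pr1 <- make_pairs(ps, refs, 200, seed = 9)
  pr2 <- make_pairs(ps, refs, 200, seed = 9)
  expect_identical(pr1, pr2)
  expect_equal(sum(pr1$label == 1), 100)
  rlab <- c(rep("benign", 2), rep("malignant", 2))
  same <- ps$label[pr1$patch] == rlab[pr1$reference]
  expect_equal(as.integer(same), pr1$label)
  only_b <- patch_set(ps$values, label = "benign", m = 8)
  expect_error(make_pairs(only_b, refs, 10, 1), "both classes")
})

test_that("zero epochs returns the untouched initialization", {
  ps <- random_patches(4, 4, 8, seed = 10)
  refs <- learn_local_references(ps, 2, 2, seed = 10)
  cfg <- train_config(epochs = 0, seed = 11)
  enc <- train_encoder(ps, refs, cfg)
  expect_equal(nrow(enc$history), 0)
  ref_enc <- init_encoder(8, hidden = cfg$hidden, seed = 11)
  expect_identical(enc$backbone$blocks[[1]]$W, ref_enc$backbone$blocks[[1]]$W)
  expect_identical(enc$head$W3, ref_enc$head$W3)
})

test_that("training separates two far-apart constant-intensity classes", {
  # benign patches near 0.1, malignant near 0.9: the relation task is
  # near-trivial, so training pair accuracy must approach 1
  withr::with_seed(12, {
    nb <- 30; nm <- 30; m <- 8
    V <- rbind(matrix(0.1 + 0.02 * runif(nb * m * m), nb, m * m),
               matrix(0.9 - 0.02 * runif(nm * m * m), nm, m * m))
  })
  ps <- patch_set(V, label = rep(c("benign", "malignant"), c(30, 30)), m = 8)
  refs <- learn_local_references(ps, 2, 2, seed = 13)
  cfg <- train_config(epochs = 8, pairs_per_epoch = 256, batch_size = 32,
                      seed = 13)
  enc <- train_encoder(ps, refs, cfg)
  expect_equal(nrow(enc$history), 8)
  expect_true(all(is.finite(enc$history$loss)))
  expect_gte(enc$history$accuracy[8], 0.95)
})

test_that("label-shuffled pairs yield chance-level pair accuracy", {
  # destroying the patch labels removes all signal the relation head could
  # exploit; final accuracy must hover around 0.5 across seeds
  accs <- sapply(1:3, function(s) {
    withr::with_seed(100 + s, {
      V <- matrix(runif(60 * 64), 60, 64)
      lab <- sample(rep(c("benign", "malignant"), 30))
    })
    ps <- patch_set(V, label = lab, m = 8)
    refs <- learn_local_references(ps, 2, 2, seed = s)
    enc <- train_encoder(ps, refs,
                         train_config(epochs = 3, pairs_per_epoch = 256,
                                      batch_size = 32, seed = s))
    enc$history$accuracy[3]
  })
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("an encoder survives a JSON save/load round trip", {
  ps <- random_patches(6, 6, 8, seed = 14)
  refs <- learn_local_references(ps, 2, 2, seed = 14)
  enc <- train_encoder(ps, refs,
                       train_config(epochs = 2, pairs_per_epoch = 64,
                                    seed = 14))
  f <- withr::local_tempfile(fileext = ".json")
  save_encoder(enc, f)
  back <- load_encoder(f)
  p <- matrix(runif(64), 8, 8)
  expect_equal(cnn_features(p, back), cnn_features(p, enc), tolerance = 1e-12)
  expect_equal(back$history$loss, enc$history$loss, tolerance = 1e-12)
  q <- matrix(runif(64), 8, 8)
  expect_equal(similarity(p, q, back), similarity(p, q, enc),
               tolerance = 1e-12)
})
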