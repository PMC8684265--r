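test_that("load_image normalizes intensities by the format maximum", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 8, 8), f1)  # all 255 in the 8-bit file
  img <- load_image(f1, label = "Benign")
  expect_equal(img$pixels, matrix(1, 8, 8))
  expect_equal(img$label, "benign")
  f0 <- file.path(d, "black.png")
  png::writePNG(matrix(0, 8, 8), f0)
  expect_equal(load_image(f0)$pixels, matrix(0, 8, 8))
})

test_that("RGB input collapses to luminance and TIFF decodes too", {
  d <- withr::local_tempdir()
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  f <- file.path(d, "rgb.png")
  png::writePNG(arr, f)
  img <- load_image(f)
  expect_equal(dim(img$pixels), c(8, 8))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  ft <- file.path(d, "gray.tiff")
  tiff::writeTIFF(matrix(runif(36), 6, 6), ft)
  expect_equal(dim(load_image(ft)$pixels), c(6, 6))
})

test_that("mask shape mismatch is rejected with both shapes named", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 64, 64), file.path(d, "img.png"))
  png::writePNG(matrix(1, 64, 48), file.path(d, "mask.png"))
  expect_error(load_image(file.path(d, "img.png"), file.path(d, "mask.png")),
               "64 x 48.*64 x 64|mask shape")
})

test_that("manifest reading enforces schema and label vocabulary", {
  d <- withr::local_tempdir()
  for (i in 1:3) png::writePNG(matrix(0.5, 8, 8), file.path(d, paste0("i", i, ".png")))
  ok <- file.path(d, "ok.csv")
  writeLines(c("image,label,mask", "i1.png,benign,", "i2.png,Malignant,",
               "i3.png,BENIGN,"), ok)
  man <- read_manifest(ok)
  expect_equal(man$label, c("benign", "malignant", "benign"))
  expect_equal(basename(man$image), c("i1.png", "i2.png", "i3.png"))
  expect_true(all(is.na(man$mask)))

  bad <- file.path(d, "bad.csv")
  writeLines(c("image,label,mask", "i1.png,benign,", "i2.png,cyst,"), bad)
  expect_error(read_manifest(bad), "row 2.*cyst")

  noco <- file.path(d, "noco.csv")
  writeLines(c("image,mask", "i1.png,"), noco)
  expect_error(read_manifest(noco), "label")
})

test_that("patch extraction walks the origin grid in row-major order", {
  img <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4))
  ps <- extract_patches(img, m = 2, stride = 2)
  expect_equal(n_patches(ps), 4)
  expect_equal(unname(ps$origin),
               rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2)))
  ps1 <- extract_patches(gray_image(matrix(runif(25), 5, 5)), m = 2, stride = 1)
  expect_equal(n_patches(ps1), 16)
})

test_that("patch values equal the parent sub-grid bit-exactly", {
  set.seed(3)
  img <- gray_image(matrix(runif(7 * 9), 7, 9), image_id = "x",
                    label = "malignant")
  ps <- extract_patches(img, m = 3, stride = 2)
  for (t in seq_len(n_patches(ps))) {
    r0 <- ps$origin[t, 1]; c0 <- ps$origin[t, 2]
    sub <- img$pixels[r0 + 1:3, c0 + 1:3]
    expect_identical(ps$values[t, ], as.vector(t(sub)))
  }
  expect_true(all(ps$label == "malignant"))
  expect_true(all(ps$image_id == "x"))
})

test_that("patch count matches the closed-form grid size on random shapes", {
  set.seed(11)
  for (i in 1:20) {
    H <- sample(8:40, 1); W <- sample(8:40, 1)
    m <- sample(2:min(H, W, 12), 1); s <- sample(1:5, 1)
    img <- gray_image(matrix(runif(H * W), H, W))
    expected <- (floor((H - m) / s) + 1) * (floor((W - m) / s) + 1)
    expect_equal(n_patches(extract_patches(img, m, s)), expected)
  }
})

test_that("ROI gating keeps only patches covered by the mask", {
  px <- matrix(runif(64), 8, 8)
  roi0 <- matrix(FALSE, 8, 8)
  img0 <- gray_image(px, roi = roi0)
  expect_equal(n_patches(extract_patches(img0, 4, 4, roi_min_frac = 0.5)), 0)
  # left half inside: patches fully in the left half survive at frac 1
  roi <- matrix(FALSE, 8, 8); roi[, 1:4] <- TRUE
  img <- gray_image(px, roi = roi)
  ps <- extract_patches(img, 4, 4, roi_min_frac = 1)
  expect_equal(unname(ps$origin), rbind(c(0, 0), c(4, 0)))
  # at frac 0 everything survives
  expect_equal(n_patches(extract_patches(img, 4, 4, roi_min_frac = 0)), 4)
})

test_that("oversized patch side and identical-input determinism behave", {
  img <- gray_image(matrix(runif(16), 4, 4))
  expect_error(extract_patches(img, m = 5), "exceeds")
  a <- extract_patches(img, 2, 1)
  b <- extract_patches(img, 2, 1)
  expect_identical(a$values, b$values)
  expect_identical(a$origin, b$origin)
})

test_that("bind_patches concatenates and subsetting preserves metadata", {
  a <- random_patches(2, 2, 3, seed = 1)
  b <- random_patches(1, 3, 3, seed = 2)
  ab <- bind_patches(a, b)
  expect_equal(n_patches(ab), 8)
  expect_equal(ab$label, c(a$label, b$label))
  sub <- ab[c(1, 8)]
  expect_equal(sub$values[2, ], b$values[4, ])
})
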