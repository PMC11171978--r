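test_that("quantization maps the 8-bit range onto the level alphabet", {
  expect_identical(quantize(matrix(255L, 4, 4), 32)[1, 1], 31L)
  expect_identical(quantize(matrix(0L, 4, 4), 7)[1, 1], 0L)
  r <- rand_region(8, 8, seed = 1)
  expect_identical(quantize(r, 256), r)        # identity at 256 levels
  expect_error(quantize(r, 1), "levels")
  expect_error(quantize(r, 300), "levels")
})

test_that("co-occurrence matrix matches brute-force pair enumeration", {
  # hand cases
  const <- matrix(3L, 5, 5)
  g <- glcm(const, levels = 8)
  expect_equal(g$p[4, 4], 1)
  expect_equal(sum(g$p), 1)

  g2 <- glcm(matrix(c(0L, 1L), 1, 2), levels = 2, angles = 0)
  expect_equal(g2$p[1, 2], 0.5)
  expect_equal(g2$p[2, 1], 0.5)

  # random regions vs oracle, several alphabets and angle subsets
  for (seed in 1:10) {
    for (ng in c(4L, 8L)) {
      r <- quantize(rand_region(6, 6, seed = seed), ng)
      for (angles in list(0, c(0, 90), c(0, 45, 90, 135))) {
        p <- glcm(r, levels = ng, angles = angles)$p
        expect_equal(p, oracle_glcm(r, ng, angles = angles),
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})

test_that("GLCM matrices normalize to 1 and are exactly symmetric", {
  for (seed in 1:200) {
    ng <- sample(c(4L, 8L, 16L, 32L), 1)
    r <- quantize(rand_region(sample(5:12, 1), sample(5:12, 1),
                              seed = 1000 + seed), ng)
    p <- glcm(r, levels = ng)$p
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_identical(max(abs(p - t(p))), 0)
  }
})

test_that("Haralick features: degenerate, checkerboard, and oracle cases", {
  # constant region at level c
  cst <- glcm_features(glcm(matrix(5L, 6, 6), levels = 8))
  expect_equal(unname(cst["glcm_contrast"]), 0)
  expect_equal(unname(cst["glcm_idm"]), 1)
  expect_equal(unname(cst["glcm_sum_average"]), 10)   # 2c
  expect_equal(unname(cst["glcm_ssq_variance"]), 0)
  expect_equal(unname(cst["glcm_difference_variance"]), 0)
  expect_true(is.na(cst["glcm_correlation"]))

  # checkerboard of levels {0, ng-1}, horizontal pairs only
  ng <- 4L
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2L) * (ng - 1L))
  f <- glcm_features(glcm(cb, levels = ng, angles = 0))
  expect_equal(unname(f["glcm_contrast"]), (ng - 1)^2)

  for (seed in 1:20) {
    ng <- c(4L, 8L, 32L)[seed %% 3 + 1]
    r <- quantize(rand_region(8, 8, seed = 2000 + seed), ng)
    m <- glcm(r, levels = ng)
    expect_equal(glcm_features(m), oracle_glcm_features(m$p),
                 tolerance = 1e-10)
  }
})

test_that("difference statistics match pair enumeration", {
  cst <- glds(matrix(7L, 5, 5), levels = 8)
  expect_equal(cst$q[1], 1)

  ramp <- matrix(0:7, 4, 8, byrow = TRUE)
  h <- glds(ramp, levels = 8, displacements = list(c(0, 1)))
  expect_equal(h$q[2], 1)                     # all horizontal diffs are 1

  for (seed in 1:10) {
    for (ng in c(4L, 8L, 32L)) {
      r <- quantize(rand_region(7, 9, seed = 3000 + seed), ng)
      expect_equal(glds(r, levels = ng)$q, oracle_glds(r, ng),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLDS features: closed forms and oracle", {
  h0 <- structure(list(q = c(1, 0, 0, 0), levels = 4L), class = "glds")
  f0 <- glds_features(h0)
  expect_equal(unname(f0), c(1, 0, 1, 0, 0))

  hu <- structure(list(q = c(0.5, 0.5), levels = 2L), class = "glds")
  fu <- glds_features(hu)
  expect_equal(unname(fu["glds_asm"]), 0.5)
  expect_equal(unname(fu["glds_entropy"]), log(2))
  expect_equal(unname(fu["glds_mean"]), 0.5)
  expect_equal(unname(fu["glds_contrast"]), 0.5)
  expect_equal(unname(fu["glds_homogeneity"]), 0.75)

  for (seed in 1:20) {
    set.seed(seed)
    q <- runif(16); q <- q / sum(q)
    h <- structure(list(q = q, levels = 16L), class = "glds")
    expect_equal(glds_features(h), oracle_glds_features(q),
                 tolerance = 1e-12)
  }
})

test_that("Haar sub-band statistics match the 2x2 block-filter oracle", {
  expect_equal(unname(haar_features(matrix(9L, 6, 6))), c(0, 0))

  # single vertical step edge, placed inside a 2x2 block so the one-level
  # transform can see it: energy lands in the column-difference band
  step <- cbind(matrix(0L, 8, 3), matrix(200L, 8, 5))
  dec <- tendonquant:::haar_decompose(step)
  expect_gt(unname(haar_features(step)["haar_mean"]), 0)
  expect_gt(sum(dec$horiz^2), sum(dec$vert^2))
  expect_gt(sum(dec$horiz^2), sum(dec$diag^2))

  for (seed in 1:20) {
    r <- rand_region(8, 8, seed = 4000 + seed)
    expect_equal(haar_features(r), oracle_haar(r), tolerance = 1e-12)
  }
  # odd dimensions are truncated, not padded
  r9 <- rand_region(9, 9, seed = 99)
  expect_equal(haar_features(r9), oracle_haar(r9), tolerance = 1e-12)
})

test_that("texture_vector returns 13 named values, flags degeneracy, is pure", {
  img <- us_image(matrix(77L, 32, 32))
  rect <- rect_roi(2, 2, 16, 16, "quality")
  tv <- texture_vector(img, rect)
  expect_identical(names(tv), tendonquant:::TEXTURE_FEATURE_NAMES)
  expect_length(tv, 13)
  expect_true(is.na(tv["glcm_correlation"]))
  expect_equal(unname(tv["glcm_contrast"]), 0)

  ph <- generate_phantom(seed = 21)
  tv1 <- texture_vector(ph$image, ph$rois$rects$quality)
  tv2 <- texture_vector(ph$image, ph$rois$rects$quality)
  expect_identical(tv1, tv2)
})

test_that("noise monotonicity: glds contrast rises, homogeneity falls", {
  amps <- c(4, 16, 40, 80, 120)
  hits <- 0; total <- 0
  for (seed in 1:20) {
    set.seed(seed)
    feats <- sapply(amps, function(a) {
      r <- matrix(pmin(pmax(round(128 + runif(24 * 24, -a, a)), 0), 255),
                  24, 24)
      q <- quantize(r, 32)
      glds_features(glds(q, 32))[c("glds_contrast", "glds_homogeneity")]
    })
    hits <- hits + sum(diff(feats["glds_contrast", ]) > 0) +
      sum(diff(feats["glds_homogeneity", ]) < 0)
    total <- total + 2 * (length(amps) - 1)
  }
  expect_gte(hits / total, 0.95)
})

test_that("texture is stable under ROI translation in stationary speckle", {
  ph <- generate_phantom(seed = 8, band_contrast = 0)  # stationary texture
  vals <- sapply(seq(0, 57, 3), function(dx) {
    r <- rect_roi(10 + dx, 30, 48, 32, "quality")
    tv <- texture_vector(ph$image, r)
    tv[c("glcm_contrast", "glds_contrast")]
  })
  cv <- apply(vals, 1, function(v) sd(v) / mean(v))
  expect_lt(max(cv), 0.1)
})
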