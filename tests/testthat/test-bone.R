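test_that("Otsu finds the valley of a bimodal region and flags degeneracy", {
  set.seed(1)
  bg <- matrix(pmin(pmax(round(rnorm(40 * 60, 40, 10)), 0), 255), 40, 60)
  region <- bg
  region[15:25, ] <- pmin(pmax(round(rnorm(11 * 60, 220, 10)), 0), 255)
  t <- otsu_threshold(region)
  expect_gte(t, 100); expect_lte(t, 180)

  seg <- segment_bone(region)
  expect_identical(seg$threshold_used, t)
  # mask equals a fixed-threshold segmentation at the returned threshold
  seg_fix <- segment_bone(region, "fixed", threshold = t)
  expect_identical(seg$mask, seg_fix$mask)

  expect_identical(otsu_threshold(matrix(128L, 8, 8)), NA_integer_)
  seg0 <- segment_bone(matrix(128L, 8, 8))
  expect_identical(seg0$n_fragments, 0L)
  expect_true(is.na(seg0$threshold_used))
})

test_that("fixed-threshold segmentation counts separated blocks", {
  region <- matrix(0L, 16, 24)
  region[3:6, 3:6] <- 255L
  region[10:13, 15:18] <- 255L
  seg <- segment_bone(region, "fixed", threshold = 128)
  expect_identical(seg$n_fragments, 2L)
  expect_identical(sum(seg$mask), 32L)

  expect_identical(segment_bone(matrix(0L, 8, 8), "fixed",
                                threshold = 128)$n_fragments, 0L)

  # min_fragment_px suppresses speckle blips
  region[1, 1] <- 255L   # isolated single pixel
  seg2 <- segment_bone(region, "fixed", threshold = 128,
                       min_fragment_px = 5)
  expect_identical(seg2$n_fragments, 2L)
  seg3 <- segment_bone(region, "fixed", threshold = 128,
                       min_fragment_px = 1)
  expect_identical(seg3$n_fragments, 3L)
})

test_that("8-connectivity joins diagonal pixels into one fragment", {
  region <- matrix(0L, 10, 10)
  for (k in 0:5) region[k + 2, k + 2] <- 255L   # diagonal staircase
  seg <- segment_bone(region, "fixed", threshold = 128, min_fragment_px = 1)
  expect_identical(seg$n_fragments, 1L)
})

test_that("bone descriptor: square and two-square closed forms", {
  region <- matrix(0L, 20, 20)
  region[5:14, 5:14] <- 255L
  seg <- segment_bone(region, "fixed", threshold = 128)
  bf <- bone_features(seg, region)
  expect_equal(unname(bf["bone_n_fragments"]), 1)
  expect_equal(unname(bf["bone_area"]), 100)
  expect_equal(unname(bf["bone_perimeter"]), 36)   # 4 * (10 - 1) unit steps
  expect_equal(unname(bf["bone_convexity"]), 1)

  two <- matrix(0L, 20, 30)
  two[5:10, 4:9] <- 255L
  two[12:17, 20:25] <- 255L
  seg2 <- segment_bone(two, "fixed", threshold = 128)
  bf2 <- bone_features(seg2, two)
  expect_equal(unname(bf2["bone_n_fragments"]), 2)
  expect_equal(unname(bf2["bone_area"]), 72)        # additive
  expect_lt(unname(bf2["bone_convexity"]), 1)       # hull spans the gap

  # empty segmentation: zero area/perimeter, convexity undefined
  bf0 <- bone_features(segment_bone(matrix(0L, 8, 8), "fixed",
                                    threshold = 128),
                       matrix(0L, 8, 8))
  expect_equal(unname(bf0["bone_area"]), 0)
  expect_equal(unname(bf0["bone_perimeter"]), 0)
  expect_true(is.na(bf0["bone_convexity"]))
})

test_that("perimeter tracks the marching-squares oracle on blobs", {
  for (seed in 1:5) {
    set.seed(seed)
    region <- matrix(0L, 48, 48)
    cx <- runif(1, 18, 30); cy <- runif(1, 18, 30); rad <- runif(1, 9, 14)
    xx <- matrix(1:48, 48, 48, byrow = TRUE)
    yy <- matrix(1:48, 48, 48)
    region[(xx - cx)^2 + (yy - cy)^2 <= rad^2] <- 255L
    seg <- segment_bone(region, "fixed", threshold = 128)
    bf <- bone_features(seg, region)
    oracle <- oracle_marching_squares_perimeter(seg$mask)
    expect_lt(abs(bf[["bone_perimeter"]] - oracle) / oracle, 0.05)
  }
})

test_that("bone texture triple uses its own homogeneity formula", {
  set.seed(3)
  region <- rand_region(24, 24, seed = 31)
  seg <- segment_bone(region, "fixed", threshold = 128)
  bf <- bone_features(seg, region, tq_config(levels = 8))
  g <- glcm(quantize(region, 8), levels = 8)
  lev <- 0:7
  hom <- sum(g$p / (1 + abs(outer(lev, lev, "-"))))
  idm <- sum(g$p / (1 + outer(lev, lev, "-")^2))
  expect_equal(unname(bf["bone_glcm_homogeneity"]), hom, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(hom, idm)))   # the two formulas differ here
  gf <- glcm_features(g)
  expect_equal(unname(bf["bone_glcm_contrast"]),
               unname(gf["glcm_contrast"]))
  expect_equal(unname(bf["bone_glcm_correlation"]),
               unname(gf["glcm_correlation"]))
})

test_that("area monotone in threshold; invariant to padding/translation", {
  region <- rand_region(30, 30, seed = 7)
  areas <- sapply(seq(20, 240, length.out = 10), function(t) {
    sum(segment_bone(region, "fixed", threshold = t,
                     min_fragment_px = 1)$mask)
  })
  expect_true(all(diff(areas) <= 0))

  blob <- matrix(0L, 20, 20)
  blob[6:12, 5:15] <- 255L
  f1 <- bone_features(segment_bone(blob, "fixed", threshold = 128), blob)
  padded <- matrix(0L, 30, 34)
  padded[9:15, 12:22] <- 255L                # same blob, shifted + padded
  f2 <- bone_features(segment_bone(padded, "fixed", threshold = 128), padded)
  expect_equal(f1[["bone_area"]], f2[["bone_area"]])
  expect_equal(f1[["bone_perimeter"]], f2[["bone_perimeter"]])
})

test_that("fragment counts are exact on seeded blob layouts", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(1:5, 1)
    region <- matrix(0L, 40, 60)
    # non-overlapping blocks on a coarse grid, separation > 1 px
    cells <- expand.grid(r = seq(2, 32, 10), c = seq(2, 52, 10))
    pick <- cells[sample(nrow(cells), k), ]
    for (i in seq_len(k)) {
      h <- sample(3:6, 1); w <- sample(3:6, 1)
      region[pick$r[i]:(pick$r[i] + h), pick$c[i]:(pick$c[i] + w)] <- 255L
    }
    seg <- segment_bone(region, "fixed", threshold = 128,
                        min_fragment_px = 5)
    expect_identical(seg$n_fragments, as.integer(k))
  }
})
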