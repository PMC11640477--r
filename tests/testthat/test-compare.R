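test_that("centroid: single voxel, symmetric sphere, L-shape vs oracle", {
  a <- array(FALSE, c(7, 7, 7)); a[3, 4, 5] <- TRUE
  m <- voxel_mask(a, spacing = c(1, 2, 3), origin = c(1, 1, 1))
  expect_equal(centroid(m), c(1 + 2 * 1, 1 + 3 * 2, 1 + 4 * 3))

  sph <- array(FALSE, c(15, 15, 15))
  cc <- 8; for (k in 1:15) for (j in 1:15) for (i in 1:15)
    sph[i, j, k] <- sum((c(i, j, k) - cc)^2) <= 36
  ms <- voxel_mask(sph)
  expect_lt(max(abs(centroid(ms) - (cc - 1))), 0.5)

  L <- array(FALSE, c(6, 6, 3)); L[1:5, 1, 1] <- TRUE; L[1, 1:4, 1] <- TRUE
  ml <- voxel_mask(L, spacing = c(1, 1.5, 2), origin = c(-1, 0, 2))
  expect_equal(centroid(ml), oracle_centroid(ml))

  expect_error(centroid(voxel_mask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("overlap indices: identity, disjoint, shifted cube, oracle, symmetry", {
  a <- array(FALSE, c(20, 12, 12)); a[3:12, 2:11, 2:11] <- TRUE
  m1 <- voxel_mask(a)
  ov <- overlap_indices(m1, m1)
  expect_equal(ov$dice, 1)
  expect_equal(ov$jaccard, 1)

  b <- array(FALSE, c(20, 12, 12)); b[8:17, 2:11, 2:11] <- TRUE  # +5 voxels
  m2 <- voxel_mask(b)
  ov2 <- overlap_indices(m1, m2)
  expect_equal(ov2$dice, 0.5)           # intersection 500 of 1000+1000
  expect_equal(ov2$jaccard, 1 / 3)
  ov2r <- overlap_indices(m2, m1)
  expect_equal(ov2r$dice, ov2$dice)
  expect_equal(ov2r$jaccard, ov2$jaccard)

  d1 <- array(FALSE, c(8, 8, 8)); d1[1:2, 1:2, 1:2] <- TRUE
  d2 <- array(FALSE, c(8, 8, 8)); d2[6:7, 6:7, 6:7] <- TRUE
  ovd <- overlap_indices(voxel_mask(d1), voxel_mask(d2))
  expect_equal(ovd$dice, 0)
  expect_equal(ovd$jaccard, 0)

  # dice = 2*jaccard / (1 + jaccard) identity on random masks
  set.seed(5)
  for (rep in 1:5) {
    x <- random_mask(); y <- random_mask()
    o <- overlap_indices(x, y)
    expect_equal(o$dice, 2 * o$jaccard / (1 + o$jaccard), tolerance = 1e-12)
    expect_lte(o$jaccard, o$dice)
    oo <- oracle_overlap(x, y)
    expect_equal(o$dice, oo$dice)
    expect_equal(o$jaccard, oo$jaccard)
  }

  ee <- voxel_mask(array(FALSE, c(3, 3, 3)))
  expect_warning(oe <- overlap_indices(ee, ee), "both masks empty")
  expect_equal(oe$dice, 1)
})

test_that("mean distance agreement: zero at identity, bounded by translation, oracle", {
  m <- random_mask(dims = c(10, 9, 8))
  expect_equal(mean_distance_agreement(m, m), 0)

  a <- array(FALSE, c(16, 10, 10)); a[3:6, 3:6, 3:6] <- TRUE
  mc <- voxel_mask(a, spacing = c(1, 1, 2))
  mt <- translate_mask(mc, c(4, 0, 0))
  mda <- mean_distance_agreement(mc, mt)
  expect_lte(mda, 4 + 1e-9)
  expect_equal(mean_distance_agreement(mt, mc), mda)  # symmetric

  # two specific slabs vs the all-pairs oracle
  s1 <- array(FALSE, c(9, 7, 6)); s1[2:4, 2:6, 2:3] <- TRUE
  s2 <- array(FALSE, c(9, 7, 6)); s2[5:8, 3:5, 3:5] <- TRUE
  w1 <- voxel_mask(s1, spacing = c(1, 1.5, 2))
  w2 <- voxel_mask(s2, spacing = c(1, 1.5, 2))
  expect_equal(mean_distance_agreement(w1, w2), oracle_mda(w1, w2),
               tolerance = 1e-9)

  expect_error(
    mean_distance_agreement(m, voxel_mask(array(FALSE, dim(m$voxels)),
                                          spacing = m$spacing)),
    "non-empty")
})

test_that("derive_margins: encompassed, S-shift, equivariance, oracle", {
  a <- array(FALSE, c(14, 14, 14)); a[4:10, 4:10, 4:10] <- TRUE
  big <- voxel_mask(a, spacing = c(1, 1, 2))
  inner <- a; inner[4, , ] <- FALSE
  small <- voxel_mask(inner, spacing = c(1, 1, 2))

  # itv1 contained in itv2 -> all margins zero
  expect_true(all(derive_margins(big, small) == 0))

  # itv1 = itv2 translated 4 mm toward S -> only the S margin is 4
  itv2 <- big
  itv1 <- translate_mask(big, c(0, 0, 4))
  mg <- derive_margins(itv2, itv1)
  expect_equal(unname(mg[["s"]]), 4)
  expect_true(all(mg[c("r", "l", "a", "p", "i")] == 0))

  # equivariance: translating itv1 a further +t along one axis adds t to
  # exactly that direction
  itv1b <- translate_mask(big, c(0, 2, 4))
  mgb <- derive_margins(itv2, itv1b)
  expect_equal(unname(mgb[["p"]]), 2)
  expect_equal(unname(mgb[["s"]]), 4)
  expect_true(all(mgb[c("r", "l", "a", "i")] == 0))

  expect_true(all(derive_margins(big, big) == 0))

  set.seed(9)
  for (rep in 1:5) {
    x <- random_mask(); y <- random_mask()
    expect_equal(as.numeric(derive_margins(x, y)),
                 unname(oracle_margins(x, y)), tolerance = 1e-9)
  }
})

test_that("pct_volume_difference conventions", {
  expect_equal(pct_volume_difference(25, 25), 0)
  expect_equal(pct_volume_difference(20, 25), -20)
  expect_equal(pct_volume_difference(1.134 * 18, 18), 13.4)
  expect_error(pct_volume_difference(10, 0), "positive")
})

test_that("compare_masks bundles the battery and is translation invariant", {
  set.seed(13)
  clear_high_border <- function(m, nv = 3) {
    dm <- dim(m$voxels)
    m$voxels[(dm[1] - nv + 1):dm[1], , ] <- FALSE
    m$voxels[, (dm[2] - nv + 1):dm[2], ] <- FALSE
    m$voxels[, , (dm[3] - nv + 1):dm[3]] <- FALSE
    if (!any(m$voxels)) m$voxels[2, 2, 2] <- TRUE
    m
  }
  x <- clear_high_border(random_mask())
  y <- clear_high_border(random_mask())
  rep1 <- compare_masks(x, y)
  expect_s3_class(rep1, "comparison_report")
  expect_equal(rep1$dice, 2 * rep1$jaccard / (1 + rep1$jaccard),
               tolerance = 1e-12)
  expect_equal(rep1$pct_diff,
               (rep1$vol2_cc - rep1$vol1_cc) / rep1$vol1_cc * 100,
               tolerance = 1e-9)

  # translating both masks identically changes nothing
  xt <- translate_mask(x, c(2, 1.5, 2))
  yt <- translate_mask(y, c(2, 1.5, 2))
  rep2 <- compare_masks(xt, yt)
  for (f in c("vol1_cc", "vol2_cc", "pct_diff", "centroid_shift_mm",
              "dice", "jaccard", "mda_mm"))
    expect_equal(rep2[[f]], rep1[[f]], tolerance = 1e-9)
})

test_that("evaluate_with_margins: encompassment and the zero-margin identity", {
  spec <- small_phantom_spec()
  pair <- generate_itv_pair(spec, dropout_phases = c(0, 1),
                            known_shift_mm = c(2, 0, -4))
  mg <- derive_margins(pair$itv2, pair$itv1)
  post <- evaluate_with_margins(pair$itv2, mg, pair$itv1)
  expect_true(all(post$encompassed))
  pre <- compare_masks(pair$itv1, pair$itv2)
  expect_gte(post$dice, pre$dice)  # empirical on this scenario

  zero <- suppressWarnings(
    evaluate_with_margins(pair$itv2, margin_vector(), pair$itv1))
  for (f in c("vol1_cc", "vol2_cc", "pct_diff", "centroid_shift_mm",
              "dice", "jaccard", "mda_mm"))
    expect_equal(zero[[f]], pre[[f]])
})
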