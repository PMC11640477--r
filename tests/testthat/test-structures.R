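test_that("voxel_mask canonicalizes axis labels; volume is conserved", {
  arr <- array(FALSE, c(5, 4, 3))
  arr[1, 2, 3] <- TRUE
  arr[4, 1, 1] <- TRUE
  m_lps <- voxel_mask(arr, spacing = c(1, 2, 3), origin = c(0, 0, 0))

  # same object stored RAS-flavoured: axes 1 and 2 reversed, labels R/A
  arr_ras <- arr[5:1, 4:1, , drop = FALSE]
  m_ras <- voxel_mask(arr_ras, spacing = c(1, 2, 3),
                      origin = c(4 * 1, 3 * 2, 0), axis_labels = c("R", "A", "S"))
  expect_true(masks_equal(m_lps, m_ras))
  expect_equal(mask_volume(m_lps), mask_volume(m_ras))

  # axis permutation: store as (z, x, y)
  arr_p <- aperm(arr, c(3, 1, 2))
  m_p <- voxel_mask(arr_p, spacing = c(3, 1, 2), origin = c(0, 0, 0),
                    axis_labels = c("S", "L", "P"))
  expect_true(masks_equal(m_lps, m_p))

  expect_error(voxel_mask(arr, axis_labels = c("L", "L", "S")), "axis")
  expect_error(voxel_mask(array(0.5, c(2, 2, 2))), "binary")
})

test_that("union_phases: identity, disjoint additivity, algebraic laws, grid checks", {
  m <- random_mask()
  expect_true(masks_equal(union_phases(list(m)), m))

  a1 <- array(FALSE, c(8, 8, 8)); a1[1:2, 1:2, 1:2] <- TRUE
  a2 <- array(FALSE, c(8, 8, 8)); a2[6:7, 6:7, 6:7] <- TRUE
  u <- union_phases(list(voxel_mask(a1), voxel_mask(a2)))
  expect_equal(mask_volume(u), sum(a1) + sum(a2))

  set.seed(42)
  for (rep in 1:5) {
    x <- random_mask(); y <- random_mask(); z <- random_mask()
    expect_true(masks_equal(union_phases(list(x, y)),
                            union_phases(list(y, x))))
    expect_true(masks_equal(union_phases(list(x, x)), x))
    expect_true(masks_equal(union_phases(list(union_phases(list(x, y)), z)),
                            union_phases(list(x, union_phases(list(y, z))))))
    expect_gte(mask_volume(union_phases(list(x, y))),
               max(mask_volume(x), mask_volume(y)))
  }

  other <- voxel_mask(array(TRUE, c(4, 4, 4)))
  expect_error(union_phases(list(m, other)), "dims")
  m2 <- m; m2$spacing <- m$spacing * 2
  expect_error(union_phases(list(m, m2)), "spacing")
})

test_that("isotropic expansion: identity at 0, ball oracle, monotone, containment", {
  m <- random_mask()
  expect_true(masks_equal(expand_isotropic(m, 0), m))

  # single voxel, 1 mm spacing, margin 5 -> exact ball of voxel centres
  a <- array(FALSE, c(13, 13, 13)); a[7, 7, 7] <- TRUE
  sv <- voxel_mask(a, spacing = c(1, 1, 1))
  e5 <- expand_isotropic(sv, 5)
  expect_identical(e5$voxels, oracle_expand_iso(sv, 5))

  set.seed(7)
  for (rep in 1:3) {
    m <- random_mask()
    e2 <- suppressWarnings(expand_isotropic(m, 2.5))
    e4 <- suppressWarnings(expand_isotropic(m, 4.5))
    expect_true(all(m$voxels <= e2$voxels))
    expect_true(all(e2$voxels <= e4$voxels))  # monotone in margin
  }

  # expansion beyond the grid warns and clips
  b <- array(FALSE, c(5, 5, 5)); b[1, 3, 3] <- TRUE
  expect_warning(expand_isotropic(voxel_mask(b), 3), "clipped")
})

test_that("anisotropic expansion: identity, single-direction growth, box oracle", {
  m <- random_mask()
  expect_true(masks_equal(expand_anisotropic(m, margin_vector()), m))

  # cube grown only toward S: S face moves, all others stay
  a <- array(FALSE, c(12, 12, 12)); a[4:8, 4:8, 4:8] <- TRUE
  cube <- voxel_mask(a, spacing = c(1, 1, 1))
  gs <- expand_anisotropic(cube, margin_vector(s = 4))
  e0 <- mask_extents(cube); e1 <- mask_extents(gs)
  expect_equal(e1[["s"]], e0[["s"]] + 4)
  for (d in c("r", "l", "a", "p", "i")) expect_equal(e1[[d]], e0[[d]])

  # equal margins m in all six directions reach the same axis extremes as
  # the isotropic expansion by m
  iso <- expand_isotropic(cube, 3)
  box <- expand_anisotropic(cube, margin_vector(3, 3, 3, 3, 3, 3))
  expect_equal(mask_extents(box), mask_extents(iso))
  expect_true(all(iso$voxels <= box$voxels))  # box contains ball

  set.seed(11)
  for (rep in 1:3) {
    m <- random_mask()
    mg <- margin_vector(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3),
                        runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3))
    expect_identical(suppressWarnings(expand_anisotropic(m, mg))$voxels,
                     oracle_expand_aniso(m, mg))
  }
})

test_that("margin_vector validation and coercion", {
  expect_error(margin_vector(r = -1), "non-negative")
  mv <- as_margin_vector(c(i = 6, s = 5, p = 4, a = 3, l = 2, r = 1))
  expect_equal(unname(mv[["s"]]), 5)
  expect_error(as_margin_vector(1:3), "interpret")
})

test_that("mask round trips through NRRD (raw/gzip/ascii) and NIfTI", {
  m <- random_mask(dims = c(9, 7, 5), spacing = c(1, 1.5, 2),
                   origin = c(-4, 3, 10))
  for (enc in c("raw", "gzip", "ascii")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_mask(m, f, encoding = enc)
    r <- read_mask(f)
    expect_identical(r$voxels, m$voxels)
    expect_lt(max(abs(r$spacing - m$spacing)), 1e-6)
    expect_lt(max(abs(r$origin - m$origin)), 1e-6)
  }
  for (ext in c(".nii", ".nii.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mask(m, f)
    r <- read_mask(f)
    expect_identical(r$voxels, m$voxels)
    expect_lt(max(abs(r$spacing - m$spacing)), 1e-6)
    expect_lt(max(abs(r$origin - m$origin)), 1e-6)
  }
})

test_that("non-binary payloads are rejected unless a threshold is given", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  # craft an ascii NRRD with values {0, 255}
  vals <- c(rep(0, 6), 255, 255)
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "space: left-posterior-superior",
               "space directions: (1,0,0) (0,1,0) (0,0,1)",
               "space origin: (0,0,0)", "encoding: ascii", "",
               paste(vals, collapse = " ")), f)
  expect_error(read_mask(f), "threshold")
  m <- read_mask(f, threshold = 0.5)
  expect_equal(sum(m$voxels), 2)
})

test_that("LPS-stored NRRD and RAS-stored volume agree in patient space", {
  # asymmetric object so any axis confusion is visible
  arr <- array(FALSE, c(6, 5, 4))
  arr[1, 1, 1] <- TRUE; arr[6, 2, 1] <- TRUE; arr[2, 5, 4] <- TRUE
  m <- voxel_mask(arr, spacing = c(1, 2, 3), origin = c(10, 20, 30))

  f_lps <- withr::local_tempfile(fileext = ".nrrd")
  write_mask(m, f_lps, encoding = "ascii")

  # same object written by hand in RAS space: flipped x/y directions and
  # origin, identical array order
  f_ras <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 6 5 4",
               "space: right-anterior-superior",
               "space directions: (-1,0,0) (0,-2,0) (0,0,3)",
               "space origin: (-10,-20,30)", "encoding: ascii", "",
               paste(as.integer(arr), collapse = " ")), f_ras)

  r_lps <- read_mask(f_lps)
  r_ras <- read_mask(f_ras)
  expect_true(masks_equal(r_lps, r_ras))
  expect_equal(mask_extents(r_lps), mask_extents(r_ras))

  # NIfTI (RAS sform) of the same object also lands on the same extents
  f_nii <- withr::local_tempfile(fileext = ".nii")
  write_mask(m, f_nii)
  expect_equal(mask_extents(read_mask(f_nii)), mask_extents(r_lps))
})

test_that("oblique orientations are rejected", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "space: left-posterior-superior",
               "space directions: (0.9,0.1,0) (0,1,0) (0,0,1)",
               "space origin: (0,0,0)", "encoding: ascii", "",
               paste(rep(1, 8), collapse = " ")), f)
  expect_error(read_mask(f), "oblique")
})

test_that("translate_mask moves by whole voxels and refuses clipping", {
  a <- array(FALSE, c(8, 8, 8)); a[4, 4, 4] <- TRUE
  m <- voxel_mask(a, spacing = c(1, 1, 2))
  t1 <- translate_mask(m, c(2, 0, 4))
  expect_true(t1$voxels[6, 4, 6])
  expect_error(translate_mask(m, c(0, 0, 40)), "off the grid")
})
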