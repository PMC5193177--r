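test_that("zero-FWHM smoothing is the identity and negative FWHM errors", {
  set.seed(1)
  m <- gm_map(array(runif(5^3), c(5, 5, 5)))
  expect_identical(gm_smooth(m, 0)$values, m$values)
  expect_error(gm_smooth(m, -1), "nonnegative")
})

test_that("smoothing matches a brute-force direct-convolution oracle", {
  set.seed(7)
  vox <- c(2, 2, 2)
  for (rep in 1:3) {
    v <- array(runif(6^3), c(6, 6, 6))
    out <- gm_smooth(gm_map(v, vox), fwhm_mm = 4, clip = FALSE)$values
    sigmas <- 4 / (vox * 2 * sqrt(2 * log(2)))   # 0.8493 voxels per axis
    expect_lt(max(abs(out - conv_oracle(v, sigmas))), 1e-10)
  }
})

test_that("smoothing is linear before clipping", {
  set.seed(11)
  X <- array(runif(6^3), c(6, 6, 6)); Y <- array(runif(6^3), c(6, 6, 6))
  a <- 0.3; b <- 0.5
  lhs <- gm_smooth(gm_map(a * X + b * Y), 5, clip = FALSE)$values
  rhs <- a * gm_smooth(gm_map(X), 5, clip = FALSE)$values +
    b * gm_smooth(gm_map(Y), 5, clip = FALSE)$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("an interior unit impulse conserves mass under smoothing", {
  v <- array(0, c(21, 21, 21)); v[11, 11, 11] <- 1
  out <- gm_smooth(gm_map(v), fwhm_mm = 6, clip = FALSE)$values
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("the gray-matter mask implements the cohort-mean threshold rule", {
  zeros <- gm_map(array(0, c(2, 2, 2)))
  ones <- gm_map(array(1, c(2, 2, 2)))
  expect_equal(build_mask(list(zeros, zeros), 0.03)$n_features, 0L)
  expect_equal(build_mask(list(ones, ones), 0.03)$n_features, 8L)
  m1 <- gm_map(array(c(0.01, 0.4), c(2, 1, 1)))
  m2 <- gm_map(array(c(0.03, 0.6), c(2, 1, 1)))
  mk <- build_mask(list(m1, m2), 0.03)     # voxel means 0.02 and 0.50
  expect_equal(mk$n_features, 1L)
  expect_identical(as.vector(mk$include), c(FALSE, TRUE))
  # per-subject variant: every subject must reach the threshold
  expect_equal(build_mask(list(m1, m2), 0.03, rule = "all")$n_features, 1L)
  expect_equal(build_mask(list(m1, m2), 0.5, rule = "all")$n_features, 0L)
  expect_error(build_mask(list(zeros, gm_map(array(0, c(3, 2, 2)))), 0.03),
               "grid")
})

test_that("raising the threshold shrinks the mask monotonically to empty", {
  set.seed(3)
  maps <- lapply(1:4, function(i) gm_map(array(runif(4^3), c(4, 4, 4))))
  ths <- c(0, 0.2, 0.5, 0.9, 1)
  nf <- vapply(ths, function(t) build_mask(maps, t)$n_features, integer(1L))
  expect_true(all(diff(nf) <= 0))
  expect_equal(nf[1L], 64L)
  maxmean <- max(Reduce(`+`, lapply(maps, `[[`, "values")) / 4)
  expect_equal(build_mask(maps, min(1, maxmean + 1e-9))$n_features, 0L)
})

test_that("feature extraction preserves order and handles degenerate masks", {
  set.seed(5)
  maps <- lapply(1:3, function(i) gm_map(array(runif(2^3), c(2, 2, 2))))
  cohort <- data.frame(subject_id = c("s1", "s2", "s3"), site = "A",
                       sex = "male", course = "excluded",
                       stringsAsFactors = FALSE)
  full <- build_mask(maps, 0)
  X <- extract_features(maps, full, cohort)
  expect_equal(dim(X), c(3L, 8L))
  expect_equal(X[2, ], as.vector(maps[[2]]$values))
  # permuting the cohort permutes rows identically
  perm <- c(3L, 1L, 2L)
  Xp <- extract_features(maps[perm], full, cohort[perm, ])
  expect_equal(Xp, X[perm, ])
  # empty mask keeps rows, zero columns
  empty <- build_mask(maps, 1)
  expect_equal(dim(extract_features(maps, empty, cohort)),
               c(3L, empty$n_features))
  expect_error(extract_features(maps, full, cohort[1:2, ]), "lengths differ")
})

test_that("gray-matter maps round-trip through NIfTI", {
  set.seed(9)
  m <- gm_map(array(runif(4^3), c(4, 4, 4)), voxel_size_mm = c(2, 2, 2.5))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_map(m, path)
  back <- read_nifti_map(path)
  expect_equal(back$values, m$values, tolerance = 1e-6)
  expect_equal(back$voxel_size_mm, m$voxel_size_mm)
  mask <- build_mask(list(m), 0.5)
  pmask <- tempfile(fileext = ".nii.gz")
  write_nifti_mask(mask, pmask)
  expect_equal(array(as.numeric(RNifti::readNifti(pmask)) > 0.5,
                     dim(mask$include)),
               mask$include)
})
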