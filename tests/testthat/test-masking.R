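# Exclusion rule, common mask, feature assembly — against exhaustive oracles.

test_that("the >15% rule excludes exactly the over-threshold subjects (170 -> 154)", {
  dims <- c(5, 5, 5)
  n_vox <- prod(dims)
  # 16 subjects with 20% NaN inside a full scope, 154 clean
  nan_idx <- c(replicate(16, sample(n_vox, round(0.2 * n_vox)),
                         simplify = FALSE),
               vector("list", 154))
  vols <- volumes_with_nans(170, dims, nan_idx, seed = 4)
  scope <- brain_mask(array(TRUE, dims))
  res <- exclude_subjects(vols, scope)
  expect_length(res$kept, 154)
  expect_length(res$excluded, 16)
  expect_equal(res$report$kept, unname(oracle_exclude(vols, scope$array, 0.15)))
})

test_that("a subject at exactly the threshold is kept (strict inequality)", {
  dims <- c(4, 5, 5)                       # 100 voxels: 15% = 15 exactly
  vols <- volumes_with_nans(3, dims, list(integer(0), 1:15, 1:16), seed = 5)
  res <- exclude_subjects(vols, brain_mask(array(TRUE, dims)))
  expect_equal(res$report$kept, c(TRUE, TRUE, FALSE))
  # and with no NaN anywhere, everyone is kept
  res2 <- exclude_subjects(volumes_with_nans(4, dims, seed = 6))
  expect_length(res2$excluded, 0)
})

test_that("common mask drops exactly the voxels NaN in any subject", {
  dims <- c(10, 1, 1)
  vols <- volumes_with_nans(3, dims, list(2L, 5L, integer(0)), seed = 7)
  m <- build_common_mask(vols, brain_mask(array(TRUE, dims)))
  expect_equal(m$voxel_count, 8)
  expect_identical(which(!m$array), c(2L, 5L))
  # no NaN: mask equals scope
  scope <- brain_mask(array(c(TRUE, FALSE), c(10, 1, 1))[1:10, , , drop = FALSE])
  m2 <- build_common_mask(volumes_with_nans(2, dims, seed = 8), scope)
  expect_identical(m2$array, scope$array)
  # one subject all-NaN: empty mask error
  allnan <- volumes_with_nans(2, dims, list(integer(0), 1:10), seed = 9)
  expect_error(build_common_mask(allnan), "empty mask")
})

test_that("infinities are treated as missing", {
  dims <- c(3, 3, 3)
  vols <- volumes_with_nans(2, dims, seed = 10)
  vols[[1]][5] <- Inf
  m <- build_common_mask(vols)
  expect_false(m$array[5])
})

test_that("feature assembly matches direct voxel lookups and round-trips", {
  dims <- c(3, 2, 2)
  vols <- volumes_with_nans(2, dims, list(3L, 3L), seed = 11)
  mask <- build_common_mask(vols)
  fm <- assemble_features(vols, mask)
  expect_equal(dim(fm$values), c(2, 11))
  for (i in 1:2) for (j in seq_len(mask$voxel_count))
    expect_identical(unname(fm$values[i, j]), vols[[i]][mask$indices[j]])
  # single subject gives a 1 x V row
  fm1 <- assemble_features(vols[1], mask)
  expect_equal(dim(fm1$values), c(1, 11))
  # roundtrip: scatter back restores masked voxels exactly
  back <- vector_to_volume(fm$values[1, ], mask, fill = NA)
  expect_identical(back[mask$indices], vols[[1]][mask$indices])
  # NaN inside the mask is a hard error
  bad_mask <- brain_mask(array(TRUE, dims))
  expect_error(assemble_features(vols, bad_mask), "mask")
})

test_that("fuzz: mask and exclusion decisions match the exhaustive oracle on 100 mini-cohorts", {
  set.seed(12)
  for (rep in 1:100) {
    dims <- sample(2:8, 3, replace = TRUE)
    n <- sample(2:10, 1)
    n_vox <- prod(dims)
    nan_idx <- lapply(seq_len(n), function(i)
      sample(n_vox, rbinom(1, n_vox, runif(1, 0, 0.3))))
    vols <- volumes_with_nans(n, dims, nan_idx, seed = 1000 + rep)
    scope_arr <- array(runif(n_vox) < 0.9, dims)
    if (!any(scope_arr)) scope_arr[1] <- TRUE
    scope <- brain_mask(scope_arr)
    thr <- runif(1, 0.05, 0.4)
    res <- exclude_subjects(vols, scope, max_nan_fraction = thr)
    expect_equal(res$report$kept, unname(oracle_exclude(vols, scope_arr, thr)))
    kept_vols <- vols[res$report$kept]
    if (length(kept_vols)) {
      oracle_arr <- oracle_common_mask(kept_vols, scope_arr)
      if (any(oracle_arr)) {
        m <- build_common_mask(kept_vols, scope)
        expect_identical(m$array, oracle_arr)
        # composition: exclusion + common mask never lets NaN through
        fm <- assemble_features(kept_vols, m)
        expect_false(anyNA(fm$values))
      } else {
        expect_error(build_common_mask(kept_vols, scope), "empty mask")
      }
    }
  }
})

test_that("adding a subject can only shrink or preserve the common mask", {
  set.seed(13)
  dims <- c(5, 5, 4)
  for (rep in 1:20) {
    nan_idx <- lapply(1:4, function(i) sample(100, sample(0:30, 1)))
    vols <- volumes_with_nans(4, dims, nan_idx, seed = 2000 + rep)
    m3 <- build_common_mask(vols[1:3])
    m4 <- tryCatch(build_common_mask(vols), error = function(e) NULL)
    if (!is.null(m4)) expect_true(all(m3$array | !m4$array))
  }
})
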