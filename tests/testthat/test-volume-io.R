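test_that("NIfTI write/read round trip is bitwise exact with metadata", {
  vol <- contrast_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                         voxel_size_mm = 3, subject_id = "s1",
                         contrast_label = "c1")
  path <- withr_local_file("roundtrip.nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "s1", "c1")
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$voxel_size_mm, 3)
  expect_s3_class(back, "contrast_volume")
})

test_that("read_volume rejects missing, 4-D and non-finite images", {
  expect_error(read_volume("no/such/file.nii", "s", "c"), "does not exist")

  p4 <- withr_local_file("fourd.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), p4)
  expect_error(read_volume(p4, "s", "c"), "expected 3-D")

  pn <- withr_local_file("nan.nii.gz")
  a <- array(1, c(3, 3, 3)); a[1] <- NaN
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), pn,
                     datatype = "double")
  expect_error(read_volume(pn, "s", "c"), "NaN")
})

test_that("resampling matches an independent trilinear oracle", {
  ## affine ramp: trilinear interpolation must reproduce it exactly at any
  ## interior physical coordinate
  d <- c(13, 11, 9)
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  ramp <- array(2 + 0.5 * g$x - 0.25 * g$y + 0.125 * g$z, d)
  vol <- contrast_volume(ramp, voxel_size_mm = 2, subject_id = "s",
                         contrast_label = "c")
  out <- resample_and_crop(vol, 3, c(6, 6, 5))
  ## world coords of output voxels (input voxel units): recompute directly
  ctr <- (d - 1) / 2
  for (a in 1:3) {
    idx <- ctr[a] + (seq_len(dim(out$voxels)[a]) - 1 -
                       (dim(out$voxels)[a] - 1) / 2) * 1.5
    assign(paste0("ax", a), idx)
  }
  gg <- expand.grid(x = ax1, y = ax2, z = ax3)
  expected <- 2 + 0.5 * gg$x - 0.25 * gg$y + 0.125 * gg$z
  expect_lt(max(abs(as.numeric(out$voxels) - expected)), 1e-6)
  ## physical centre preserved within one output voxel
  mid_world_in <- ctr * 2
  mid_world_out <- (c(mean(range(ax1)), mean(range(ax2)),
                      mean(range(ax3)))) * 2
  expect_true(all(abs(mid_world_in - mid_world_out) <= 3))
})

test_that("resampling: identity transform and oversize crop error", {
  v <- contrast_volume(array(rnorm(60), c(3, 4, 5)), voxel_size_mm = 3,
                       subject_id = "s", contrast_label = "c")
  same <- resample_and_crop(v, 3, c(3, 4, 5))
  expect_equal(same$voxels, v$voxels, tolerance = 1e-12)
  expect_error(resample_and_crop(v, 3, c(10, 4, 5)), "exceeds")
  expect_error(resample_and_crop(v, 2, c(3, 4, 5)), "upsampling")
})

test_that("normalizer: hand arithmetic, floors, round trip, no refit", {
  mk <- function(val) contrast_volume(array(val, c(2, 2, 2)), 3,
                                      subject_id = paste0("s", val),
                                      contrast_label = "c")
  a <- mk(1); b <- mk(3)
  a$voxels[1] <- 1; b$voxels[1] <- 3          # varying site
  a$voxels[2] <- 7; b$voxels[2] <- 7          # constant site
  norm <- fit_normalizer(list(a, b), std_floor = 1e-6)
  expect_equal(norm$mean[1], 2)
  expect_equal(norm$sd[1], 1)                 # population sd of {1, 3}
  expect_equal(norm$sd[2], 1e-6)              # floored
  na <- apply_normalizer(norm, a)
  expect_equal(na$voxels[2], 0)               # constant site maps to 0
  back <- invert_normalizer(norm, na)
  expect_lt(max(abs(back$voxels - a$voxels)), 1e-6)

  ## applying train statistics to a new volume must not refit
  c3 <- mk(5)
  nc <- apply_normalizer(norm, c3)
  expect_equal(nc$voxels[1], (5 - 2) / 1)

  ## after normalizing the training set, per-voxel mean ~0 / sd ~1
  vm <- latentmap:::as_voxel_matrix(list(apply_normalizer(norm, a),
                                         apply_normalizer(norm, b)))
  expect_lt(max(abs(rowMeans(vm$mat))), 1e-12)
  site_sd <- sqrt(rowMeans((vm$mat - rowMeans(vm$mat))^2))
  expect_equal(site_sd[1], 1, tolerance = 1e-12)
})

test_that("normalization is idempotent on already-normalized data", {
  co <- tiny_cohort()
  norm <- fit_normalizer(co$scans)
  sn <- apply_normalizer(norm, co$scans)
  norm2 <- fit_normalizer(sn)
  sn2 <- apply_normalizer(norm2, sn)
  d <- max(abs(sn2$volume[[1]]$voxels - sn$volume[[1]]$voxels))
  expect_lt(d, 1e-6)
})

test_that("subject-level split partitions subjects with balanced folds", {
  subjects <- sprintf("s%03d", 1:468)
  folds <- subject_level_split(subjects, k = 5, seed = 3)
  sizes <- as.integer(table(folds$fold))
  expect_true(all(sizes %in% c(93, 94)))
  expect_setequal(folds$subject_id, subjects)
  expect_no_subject_overlap(folds)

  again <- subject_level_split(subjects, k = 5, seed = 3)
  expect_identical(as.data.frame(folds), as.data.frame(again))
  other <- subject_level_split(subjects, k = 5, seed = 4)
  expect_false(identical(folds$fold, other$fold))

  expect_error(subject_level_split(c("a", "a", "b"), 2), "duplicate")
  expect_error(subject_level_split(c("a", "b"), 5), "between 2")

  path <- withr_local_file("folds.json")
  write_fold_assignment(folds, path)
  back <- read_fold_assignment(path)
  expect_equal(back$fold, folds$fold)
  expect_equal(attr(back, "k"), 5L)
})

test_that("demographics validation catches malformed tables", {
  expect_error(latentmap:::validate_demographics(
    tibble::tibble(subject_id = "a", age = 30)), "columns")
  expect_error(latentmap:::validate_demographics(
    tibble::tibble(subject_id = c("a", "a"), age = c(30, 31),
                   sex = c(0, 1))), "one row")
  expect_error(latentmap:::validate_demographics(
    tibble::tibble(subject_id = "a", age = -1, sex = 0)), "finite")
  expect_error(latentmap:::validate_demographics(
    tibble::tibble(subject_id = "a", age = 30, sex = 2)), "0/1")
})
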