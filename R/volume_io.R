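#' Construct a contrast volume
#'
#' A `contrast_volume` bundles one 3-D grid of activation values (for
#' example a task-fMRI contrast map in a common reference space) with the
#' metadata every downstream stage needs: who was scanned, which contrast
#' the map summarises, which cohort it belongs to, and the physical voxel
#' size.
#'
#' @param voxels 3-D numeric array of activation values; all values must be
#'   finite.
#' @param voxel_size_mm Physical voxel edge length in millimetres (scalar,
#'   isotropic).
#' @param subject_id,contrast_label Non-empty strings identifying the scan.
#' @param cohort Free-form cohort tag (default `"cohort"`).
#' @return An object of class `contrast_volume`.
#' @export
contrast_volume <- function(voxels, voxel_size_mm = 3,
                            subject_id, contrast_label,
                            cohort = "cohort") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("`voxels` must be a 3-D array")
  if (!all(is.finite(voxels)))
    abort("`voxels` contains non-finite values")
  if (!is.character(subject_id) || !nzchar(subject_id))
    abort("`subject_id` must be a non-empty string")
  if (!is.character(contrast_label) || !nzchar(contrast_label))
    abort("`contrast_label` must be a non-empty string")
  stopifnot(is.numeric(voxel_size_mm), voxel_size_mm > 0)
  structure(
    list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm[1]),
         subject_id = subject_id, contrast_label = contrast_label,
         cohort = cohort),
    class = "contrast_volume")
}

#' @export
print.contrast_volume <- function(x, ...) {
  cat(sprintf("<contrast_volume> %s / %s [%s]  %s @ %.3g mm\n",
              x$subject_id, x$contrast_label, x$cohort,
              paste(dim(x$voxels), collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' @export
dim.contrast_volume <- function(x) dim(x$voxels)

#' Read a 3-D NIfTI volume with scan metadata
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param subject_id,contrast_label,cohort Scan metadata tags.
#' @return A [contrast_volume()]. Voxels are returned in the file's stored
#'   orientation; the voxel size is read from the header.
#' @export
read_volume <- function(path, subject_id, contrast_label,
                        cohort = "cohort") {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    abort(paste0("expected 3-D volume, got ", length(d), "-D image: ", path))
  }
  vox <- array(as.numeric(img), d[1:3])
  if (anyNA(vox) || !all(is.finite(vox)))
    abort(paste0("volume contains NaN/Inf voxels: ", path))
  pd <- RNifti::pixdim(img)
  contrast_volume(vox, voxel_size_mm = pd[1], subject_id = subject_id,
                  contrast_label = contrast_label, cohort = cohort)
}

#' Write a contrast volume to NIfTI
#'
#' @param vol A [contrast_volume()].
#' @param path Output path (`.nii` or `.nii.gz`). Voxels are stored as
#'   64-bit floats so a write/read round-trip is bitwise exact.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "contrast_volume"))
  img <- RNifti::asNifti(
    vol$voxels,
    reference = list(pixdim = c(-1, rep(vol$voxel_size_mm, 3), 0, 0, 0, 0)))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

## Trilinear interpolation of `arr` at fractional 0-based voxel coordinates;
## points outside the grid evaluate to 0 (the background of a cropped map).
trilinear_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0;  fy <- yi - y0;  fz <- zi - z0
  val <- numeric(length(xi))
  at <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
      iz >= 0 & iz <= d[3] - 1
    out <- numeric(length(ix))
    idx <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
    out[ok] <- arr[idx]
    out
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    val <- val + wgt * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

#' Resample a volume to a coarser grid and crop to a target shape
#'
#' Resamples with trilinear interpolation to `target_voxel_mm` and extracts
#' a window of `target_shape` voxels. With `crop = "center"` the output grid
#' is placed so that its physical centre coincides with the input's physical
#' centre (reproducible without a brain mask); `crop = "bbox"` instead
#' centres the window on the bounding box of non-zero voxels.
#'
#' @param vol A [contrast_volume()].
#' @param target_voxel_mm Output voxel size; must not be finer than the
#'   input voxel size.
#' @param target_shape Integer triple, e.g. `c(56, 64, 56)`.
#' @param crop `"center"` (default) or `"bbox"`.
#' @return A [contrast_volume()] with `dim(vol) == target_shape`.
#' @export
resample_and_crop <- function(vol, target_voxel_mm, target_shape,
                              crop = c("center", "bbox")) {
  stopifnot(inherits(vol, "contrast_volume"))
  crop <- match.arg(crop)
  v_in <- vol$voxel_size_mm
  if (target_voxel_mm < v_in - 1e-9)
    abort("`target_voxel_mm` must be >= the input voxel size (no upsampling)")
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  d_in <- dim(vol$voxels)
  n_res <- floor((d_in - 1) * v_in / target_voxel_mm) + 1
  if (any(target_shape > n_res))
    abort(sprintf(
      "target_shape (%s) exceeds the resampled grid (%s)",
      paste(target_shape, collapse = "x"), paste(n_res, collapse = "x")))

  centre_idx <- if (crop == "center") {
    (d_in - 1) / 2
  } else {
    nz <- which(vol$voxels != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) (d_in - 1) / 2
    else (apply(nz, 2, min) + apply(nz, 2, max)) / 2 - 1
  }
  ratio <- target_voxel_mm / v_in
  ax <- function(a) centre_idx[a] + (seq_len(target_shape[a]) - 1 -
                                       (target_shape[a] - 1) / 2) * ratio
  g <- expand.grid(x = ax(1), y = ax(2), z = ax(3))
  out <- array(trilinear_sample(vol$voxels, g$x, g$y, g$z), target_shape)
  contrast_volume(out, voxel_size_mm = target_voxel_mm,
                  subject_id = vol$subject_id,
                  contrast_label = vol$contrast_label, cohort = vol$cohort)
}

## Coerce a scan tibble (list-column `volume`) or list of contrast_volumes
## to a voxel matrix (n_voxels x n_scans) plus the common shape.
as_voxel_matrix <- function(volumes) {
  vols <- if (is_tibble(volumes)) volumes$volume else volumes
  arrs <- lapply(vols, function(v)
    if (inherits(v, "contrast_volume")) v$voxels else v)
  shp <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), shp))
    abort("volumes have mismatching shapes")
  list(mat = vapply(arrs, as.numeric, numeric(prod(shp))), shape = shp)
}

#' Fit a per-voxel normalizer on training volumes
#'
#' Computes the per-voxel mean and standard deviation over a training set so
#' that each voxel (feature) can be scaled to zero mean and unit variance.
#' Voxels whose standard deviation falls below `std_floor` (e.g. constant
#' background outside the brain) have their deviation replaced by the floor.
#'
#' @param volumes List of [contrast_volume()]s, a scan tibble with a
#'   `volume` list-column, or a numeric matrix (voxels x scans).
#' @param std_floor Lower bound on the per-voxel standard deviation.
#' @return An object of class `voxel_normalizer` with fields `mean`, `sd`
#'   (floored), `shape` and `std_floor`.
#' @export
fit_normalizer <- function(volumes, std_floor = 1e-6) {
  stopifnot(std_floor > 0)
  vm <- as_voxel_matrix(volumes)
  if (ncol(vm$mat) < 2) abort("need at least 2 training volumes")
  mu <- rowMeans(vm$mat)
  s <- sqrt(rowMeans((vm$mat - mu)^2))   # population sd: scaling, not inference
  structure(list(mean = array(mu, vm$shape),
                 sd = array(pmax(s, std_floor), vm$shape),
                 shape = vm$shape, std_floor = std_floor),
            class = "voxel_normalizer")
}

#' Apply (or invert) a fitted per-voxel normalizer
#'
#' `apply_normalizer()` maps voxels to `(x - mean) / sd` using the training
#' statistics only; `invert_normalizer()` maps back. Both accept a single
#' [contrast_volume()], a bare array, or a scan tibble with a `volume`
#' list-column.
#'
#' @param norm A `voxel_normalizer` from [fit_normalizer()].
#' @param x Volume(s) to transform.
#' @return Same container type as `x`.
#' @export
apply_normalizer <- function(norm, x) normalizer_transform(norm, x, FALSE)

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(norm, x) normalizer_transform(norm, x, TRUE)

normalizer_transform <- function(norm, x, invert) {
  stopifnot(inherits(norm, "voxel_normalizer"))
  one <- function(v) {
    if (inherits(v, "contrast_volume")) {
      if (!identical(dim(v$voxels), norm$shape))
        abort("volume shape does not match the normalizer")
      v$voxels <- if (invert) v$voxels * norm$sd + norm$mean
                  else (v$voxels - norm$mean) / norm$sd
      v
    } else {
      if (!identical(dim(v), norm$shape))
        abort("array shape does not match the normalizer")
      if (invert) v * norm$sd + norm$mean else (v - norm$mean) / norm$sd
    }
  }
  if (is_tibble(x)) {
    x$volume <- lapply(x$volume, one)
    x
  } else if (inherits(x, "contrast_volume") || is.array(x)) {
    one(x)
  } else {
    lapply(x, one)
  }
}

#' Subject-level cross-validation folds
#'
#' Assigns whole subjects to `k` folds (seeded random permutation followed
#' by round-robin assignment) so that every scan of a subject inherits one
#' fold and no subject can contribute scans to both sides of a split. Fold
#' sizes differ by at most one subject.
#'
#' @param subjects Character vector of unique subject IDs.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the permutation.
#' @return A tibble (class `fold_assignment`) with columns `subject_id` and
#'   `fold` (0-based fold index), plus attributes `k` and `seed`.
#' @export
subject_level_split <- function(subjects, k, seed = 1L) {
  if (anyDuplicated(subjects)) abort("duplicate subject IDs")
  k <- as.integer(k)
  if (k < 2L || k > length(subjects))
    abort("`k` must be between 2 and the number of subjects")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  shuffled <- sample(subjects)
  out <- tibble(subject_id = shuffled,
                fold = (seq_along(shuffled) - 1L) %% k)
  out <- out[order(out$subject_id), ]
  structure(out, k = k, seed = as.integer(seed),
            class = c("fold_assignment", class(out)))
}

#' @rdname subject_level_split
#' @param folds A `fold_assignment`.
#' @param path JSON file path.
#' @export
write_fold_assignment <- function(folds, path) {
  jsonlite::write_json(
    list(k = attr(folds, "k"), seed = attr(folds, "seed"),
         subject_to_fold = setNames(as.list(folds$fold), folds$subject_id)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname subject_level_split
#' @export
read_fold_assignment <- function(path) {
  j <- jsonlite::read_json(path)
  out <- tibble(subject_id = names(j$subject_to_fold),
                fold = as.integer(unlist(j$subject_to_fold)))
  structure(out, k = as.integer(j$k), seed = as.integer(j$seed),
            class = c("fold_assignment", class(out)))
}

#' Read demographics and scan manifests
#'
#' Demographics are a TSV with columns `subject_id`, `age` (years, > 0) and
#' `sex` (0/1). A scan manifest is a TSV with columns `subject_id`,
#' `contrast_label` and `path`; [read_scan_table()] loads every listed
#' NIfTI into a scan tibble with a `volume` list-column.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_demographics <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(subject_id = "c"))
  validate_demographics(d)
  d
}

validate_demographics <- function(d) {
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(d)))
    abort("demographics need columns subject_id, age, sex")
  if (anyDuplicated(d$subject_id)) abort("one row per subject required")
  if (!all(is.finite(d$age)) || any(d$age <= 0))
    abort("ages must be finite and > 0")
  if (!all(d$sex %in% c(0, 1))) abort("sex must be coded 0/1")
  invisible(d)
}

#' @rdname read_demographics
#' @param cohort Cohort tag attached to every loaded volume.
#' @export
read_scan_table <- function(path, cohort = "cohort") {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(subject_id = "c"))
  if (!all(c("subject_id", "contrast_label", "path") %in% names(m)))
    abort("manifest needs columns subject_id, contrast_label, path")
  base <- dirname(path)
  vols <- purrr::pmap(m, function(subject_id, contrast_label, path, ...) {
    p <- if (file.exists(path)) path else file.path(base, path)
    read_volume(p, subject_id, contrast_label, cohort)
  })
  tibble(subject_id = m$subject_id, contrast_label = m$contrast_label,
         cohort = cohort, volume = vols)
}

## RNG bookkeeping: seeded operations must not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
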