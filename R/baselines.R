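#' Linear basis representations: PCA, ICA, two-stage PCA
#'
#' Reference representations that run through the identical downstream
#' pipeline as the autoencoder latents. `fit_pca()` takes the top-k
#' principal components of the centred, flattened training volumes;
#' `fit_ica()` extracts k independent components after PCA whitening;
#' `fit_two_stage_pca()` follows PCA with per-component ordinary least
#' squares of the scores on age and sex, storing both the fitted
#' (demographic) and residual score subspaces -- a linear benchmark that,
#' like the semi-supervised autoencoder, is demographic-aware. The
#' two-stage construction is this package's concrete reading of an
#' otherwise loosely specified linear benchmark.
#'
#' @param volumes Scan tibble, list of [contrast_volume()]s, or a numeric
#'   matrix (voxels x scans) of *normalized* training data.
#' @param k Number of components (default 100; reduced with a warning when
#'   the training set is too small).
#' @param seed Seed for the ICA rotation.
#' @param demographics Demographics tibble covering every training scan
#'   (two-stage PCA only).
#' @return A `linear_basis` with fields `method`, `components`
#'   (k x voxels), `center`, `k`, `shape`, `explained_variance` (PCA), and
#'   for two-stage PCA a `stage2` list of per-component OLS fits.
#' @export
fit_pca <- function(volumes, k = 100) {
  vm <- as_voxel_matrix_any(volumes)
  X <- t(vm$mat)                       # scans x voxels
  n <- nrow(X)
  if (n < 2) abort("need at least 2 training volumes")
  if (all(apply(X, 2, sd) < 1e-14)) abort("degenerate training data")
  if (k >= n) {
    warn(sprintf("k reduced from %d to %d (only %d training scans)",
                 k, n - 1, n))
    k <- n - 1
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(method = "pca",
                 components = t(pc$rotation),          # k x voxels
                 center = pc$center, k = k, shape = vm$shape,
                 explained_variance = pc$sdev[seq_len(k)]^2,
                 total_variance = sum(pc$sdev^2)),
            class = "linear_basis")
}

#' @rdname fit_pca
#' @export
fit_ica <- function(volumes, k = 100, seed = 1L) {
  vm <- as_voxel_matrix_any(volumes)
  X <- t(vm$mat)
  n <- nrow(X)
  if (k >= n) {
    warn(sprintf("k reduced from %d to %d (only %d training scans)",
                 k, n - 1, n))
    k <- n - 1
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  dec <- ica::icafast(Xc, nc = k, center = FALSE)
  ## X ~ S %*% t(M); projection of new data: scores = Xc %*% M (M'M)^-1
  M <- dec$M
  if (!is.matrix(M) || nrow(M) != ncol(Xc)) M <- matrix(t(M), ncol = k)
  proj <- M %*% pinv(crossprod(M))
  structure(list(method = "ica", components = t(proj), center = ctr,
                 mixing = M, k = k, shape = vm$shape,
                 converged = dec$converged %||% NA),
            class = "linear_basis")
}

#' @rdname fit_pca
#' @export
fit_two_stage_pca <- function(volumes, demographics, k = 100) {
  scans <- if (is_tibble(volumes)) volumes else
    abort("two-stage PCA needs a scan tibble (for subject matching)")
  demo <- match_demographics(scans, demographics)
  basis <- fit_pca(scans, k = k)
  scores <- project_scores(basis, scans)          # scans x k
  stage2 <- lapply(seq_len(ncol(scores)), function(j) {
    fit <- lm(scores[, j] ~ demo$age + demo$sex)
    list(coef = coef(fit),
         se = summary(fit)$coefficients[, "Std. Error"],
         r_squared = summary(fit)$r.squared)
  })
  basis$method <- "two_stage_pca"
  basis$stage2 <- stage2
  basis$stage2_r_squared <- vapply(stage2, `[[`, numeric(1), "r_squared")
  basis
}

## Moore-Penrose pseudo-inverse of a small symmetric matrix.
pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

## Accept matrix / tibble / list inputs uniformly.
as_voxel_matrix_any <- function(volumes) {
  if (is.matrix(volumes)) list(mat = volumes, shape = c(nrow(volumes), 1L, 1L))
  else as_voxel_matrix(volumes)
}

#' @export
print.linear_basis <- function(x, ...) {
  cat(sprintf("<linear_basis> %s, k = %d, voxels = %d\n",
              x$method, x$k, ncol(x$components)))
  invisible(x)
}

## Scores of scans in a linear basis (scans x k).
project_scores <- function(basis, volumes) {
  vm <- as_voxel_matrix_any(volumes)
  Xc <- sweep(t(vm$mat), 2, basis$center)
  Xc %*% t(basis$components)
}

#' Project scans onto a fitted linear basis
#'
#' @param basis A `linear_basis`.
#' @param scans Scan tibble in normalized space.
#' @return Latent-record-style tibble (`subject_id`, `contrast_label`,
#'   `z_latent` list-column), directly consumable by [fit_umap()] and the
#'   rest of the downstream chain.
#' @export
project_basis <- function(basis, scans) {
  stopifnot(inherits(basis, "linear_basis"), is_tibble(scans))
  sc <- project_scores(basis, scans)
  tibble(subject_id = scans$subject_id,
         contrast_label = scans$contrast_label,
         z_latent = lapply(seq_len(nrow(sc)), function(i) sc[i, ]))
}

#' Reconstruct volumes from basis scores
#'
#' @param basis A `linear_basis`.
#' @param scores Scans x k score matrix from [project_basis()] internals.
#' @return Voxels x scans matrix in normalized space.
#' @export
basis_reconstruct <- function(basis, scores) {
  t(scores %*% basis$components) + basis$center
}

#' Region-of-interest mean activations
#'
#' @param vol A [contrast_volume()] or 3-D array.
#' @param atlas Integer label array of the same shape (0 = background).
#' @return Named numeric vector of per-label means, ordered by label;
#'   labels with no voxels yield `NA` with a warning.
#' @export
roi_features <- function(vol, atlas) {
  v <- if (inherits(vol, "contrast_volume")) vol$voxels else vol
  if (!identical(dim(v), dim(atlas)))
    abort("atlas shape does not match the volume")
  labs <- sort(unique(as.integer(atlas[atlas > 0])))
  if (length(labs) == 0) abort("atlas has no nonzero labels")
  out <- vapply(labs, function(l) {
    sel <- atlas == l
    if (!any(sel)) NA_real_ else mean(v[sel])
  }, numeric(1))
  if (anyNA(out)) warn("empty ROI label(s) produced NA features")
  nms <- attr(atlas, "labels")
  names(out) <- if (!is.null(nms) && length(nms) >= max(labs))
    nms[labs] else paste0("roi_", labs)
  out
}

#' @rdname roi_features
#' @param scans Scan tibble.
#' @return For `roi_scans()`: latent-record-style tibble with the ROI
#'   feature vector per scan in `z_latent`.
#' @export
roi_scans <- function(scans, atlas) {
  feats <- lapply(scans$volume, roi_features, atlas = atlas)
  tibble(subject_id = scans$subject_id,
         contrast_label = scans$contrast_label,
         z_latent = feats)
}

#' Run a baseline representation through the identical downstream chain
#'
#' Projects the cohort onto the given representation (linear basis or ROI
#' atlas) and then calls exactly the same [downstream_chain()] used for
#' autoencoder latents: UMAP embedding fitted on training scans, normative
#' model per embedding component, latent indices, Spearman/Bonferroni
#' associations. Results are therefore comparable row-for-row with the
#' autoencoder pipeline.
#'
#' @param representation A `linear_basis` or an integer atlas array.
#' @param scans Normalized scan tibble.
#' @param demographics,nidps,nidp_meta Cohort tables.
#' @param train_subjects Subject IDs used to fit the embedder and the
#'   normative models.
#' @param ... Passed to [downstream_chain()] (UMAP parameters, normative
#'   config, alpha).
#' @return See [downstream_chain()].
#' @export
baseline_pipeline <- function(representation, scans, demographics, nidps,
                              nidp_meta = NULL, train_subjects, ...) {
  latents <- if (inherits(representation, "linear_basis"))
    project_basis(representation, scans)
  else
    roi_scans(scans, representation)
  downstream_chain(latents, demographics, nidps, nidp_meta = nidp_meta,
                   train_subjects = train_subjects, ...)
}
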