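#' Fit a UMAP embedder on training latent vectors
#'
#' Projects the latent space to a low-dimensional manifold with UMAP.
#' Defaults follow the standard settings: local neighbourhood size 15,
#' minimum embedding distance 0.1, two output components, Euclidean
#' metric. The embedder is fitted on *training* latents only and then
#' applied unchanged to test latents ([transform_latents()]); the
#' algorithm is stochastic, so the seed is fixed and recorded.
#'
#' @param latents Latent record tibble from [encode_scans()] (or a bare
#'   numeric matrix, rows = scans).
#' @param n_neighbors Size of the local neighbourhood (default 15).
#' @param min_dist Minimum distance between embedded points (default 0.1).
#' @param n_components Embedding dimensionality (default 2).
#' @param metric Distance metric (default `"euclidean"`).
#' @param seed Integer seed (default 42).
#' @return An `embedder_model` whose `$embedding` holds the fitted
#'   training coordinates.
#' @export
fit_umap <- function(latents, n_neighbors = 15, min_dist = 0.1,
                     n_components = 2, metric = "euclidean", seed = 42L) {
  X <- if (is.matrix(latents)) latents else latent_matrix(latents)
  if (nrow(X) < n_neighbors + 1)
    abort(sprintf("need at least n_neighbors + 1 = %d training points",
                  n_neighbors + 1))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  m <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                  n_components = n_components, metric = metric,
                  n_threads = 1, n_sgd_threads = 0, ret_model = TRUE)
  structure(list(model = m, n_neighbors = n_neighbors,
                 min_dist = min_dist, n_components = n_components,
                 metric = metric, seed = as.integer(seed),
                 embedding = m$embedding, n_train = nrow(X)),
            class = "embedder_model")
}

#' @export
print.embedder_model <- function(x, ...) {
  cat(sprintf(
    "<embedder_model> UMAP: %d comps, n_neighbors %d, min_dist %.3g, %s; fitted on %d points\n",
    x$n_components, x$n_neighbors, x$min_dist, x$metric, x$n_train))
  invisible(x)
}

#' Project latent records through a fitted embedder
#'
#' Applies the fitted UMAP model to new latent vectors without refitting
#' (fit-once / transform-many).
#'
#' @param embedder An `embedder_model` from [fit_umap()].
#' @param latents Latent record tibble or numeric matrix.
#' @return Tibble with `subject_id`, `contrast_label` (when available) and
#'   `umap1`, `umap2`, ... coordinates.
#' @export
transform_latents <- function(embedder, latents) {
  stopifnot(inherits(embedder, "embedder_model"))
  X <- if (is.matrix(latents)) latents else latent_matrix(latents)
  if (ncol(X) != ncol(embedder$model$embedding) &&
      !is.null(embedder$model$metric$euclidean$ndim)) {
    nd <- embedder$model$metric$euclidean$ndim
    if (ncol(X) != nd)
      abort(sprintf("latent dimension %d does not match the fitted %d",
                    ncol(X), nd))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(embedder$seed)
  co <- uwot::umap_transform(X, embedder$model, n_threads = 1,
                             n_sgd_threads = 0)
  out <- as_tibble(setNames(as.data.frame(co),
                            paste0("umap", seq_len(ncol(co)))))
  if (is_tibble(latents) && all(c("subject_id", "contrast_label") %in%
                                  names(latents)))
    out <- bind_cols(latents[, c("subject_id", "contrast_label")], out)
  out
}

#' Per-class centroids of the latent space
#'
#' Arithmetic mean of the latent vectors within each group (by default the
#' contrast label), computed in the full latent space rather than the
#' embedded space so the centroids can be decoded back to volumes.
#'
#' @param latents Latent record tibble from [encode_scans()].
#' @param by Grouping column (default `"contrast_label"`).
#' @return Named list mapping each group label to its mean latent vector.
#' @export
class_centroid <- function(latents, by = "contrast_label") {
  stopifnot(is_tibble(latents), by %in% names(latents))
  if (nrow(latents) == 0) abort("empty group in centroid computation")
  groups <- split(latents$z_latent, latents[[by]])
  if (any(lengths(groups) == 0)) abort("empty group in centroid computation")
  lapply(groups, function(g) colMeans(do.call(rbind, g)))
}

#' Decode class centroids to volumes in original units
#'
#' Runs each centroid through the decoder and un-normalizes the result, so
#' the synthetic activation pattern of each class can be inspected (or
#' compared with a ground-truth template).
#'
#' @param model A trained `trained_ae`.
#' @param centroids Named list of latent vectors ([class_centroid()]).
#' @param normalizer The cohort's `voxel_normalizer` (`NULL` to stay in
#'   normalized space).
#' @return Named list of 3-D arrays.
#' @export
decode_centroids <- function(model, centroids, normalizer = NULL) {
  vols <- decode_latent(model, centroids)
  names(vols) <- names(centroids)
  if (!is.null(normalizer))
    vols <- lapply(vols, function(v) invert_normalizer(normalizer, v))
  vols
}

#' Decode a linear traversal between two latent vectors
#'
#' Decodes `(1 - t) * z_a + t * z_b` at `steps` evenly spaced values of
#' `t` in `[0, 1]`; the endpoints equal `decode(z_a)` and `decode(z_b)`.
#' Walking the manifold this way visualises how one representation morphs
#' into another.
#'
#' @param model A trained `trained_ae`.
#' @param z_a,z_b Latent vectors of length `latent_dim`.
#' @param steps Number of frames (>= 2).
#' @return List of 3-D arrays (normalized space), ordered from `z_a` to
#'   `z_b`.
#' @export
traverse_latent <- function(model, z_a, z_b, steps = 7) {
  if (steps < 2) abort("`steps` must be >= 2")
  tt <- seq(0, 1, length.out = steps)
  zs <- lapply(tt, function(t) (1 - t) * z_a + t * z_b)
  decode_latent(model, zs)
}

#' Map embedding-space points back to nearest latent records
#'
#' Approximate inverse of the embedding: each query point in UMAP space is
#' matched to the nearest embedded record and that record's latent vector
#' is returned. Useful for decoding a grid over the embedding; the mapping
#' is approximate because UMAP has no exact inverse.
#'
#' @param embeddings Embedding tibble ([transform_latents()]).
#' @param latents Matching latent record tibble.
#' @param coords Numeric matrix of query points (columns = components).
#' @return List of latent vectors, one per query row.
#' @export
nearest_latent <- function(embeddings, latents, coords) {
  emb <- as.matrix(embeddings[, grep("^umap", names(embeddings))])
  coords <- matrix(coords, ncol = ncol(emb))
  lapply(seq_len(nrow(coords)), function(i) {
    d2 <- rowSums((emb - matrix(coords[i, ], nrow(emb), ncol(emb),
                                byrow = TRUE))^2)
    latents$z_latent[[which.min(d2)]]
  })
}

#' Mean silhouette width of embedded points by class
#'
#' Convenience wrapper around [cluster::silhouette()] on the Euclidean
#' distances of embedding coordinates, used to quantify how well the
#' embedding separates contrast classes.
#'
#' @param embeddings Embedding tibble with `umap*` columns.
#' @param labels Class label per row (defaults to `contrast_label`).
#' @return Mean silhouette width (scalar).
#' @export
embedding_silhouette <- function(embeddings,
                                 labels = embeddings$contrast_label) {
  co <- as.matrix(embeddings[, grep("^umap", names(embeddings))])
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) abort("need at least two classes")
  sil <- cluster::silhouette(cl, stats::dist(co))
  mean(sil[, "sil_width"])
}

#' @method autoplot embedder_model
#' @export
autoplot.embedder_model <- function(object, labels = NULL, ...) {
  d <- as_tibble(setNames(as.data.frame(object$embedding),
                          paste0("umap", seq_len(object$n_components))))
  if (!is.null(labels)) d$label <- labels
  p <- ggplot(d, aes(x = .data$umap1, y = .data$umap2))
  p <- if (is.null(labels)) p + geom_point(alpha = 0.6)
       else p + geom_point(aes(colour = .data$label), alpha = 0.6) +
         scale_colour_viridis_d()
  p + labs(x = "UMAP 1", y = "UMAP 2") + theme_minimal()
}
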