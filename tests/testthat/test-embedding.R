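## Three well-separated Gaussian clusters in a 100-d latent space.
cluster_latents <- function(n_per = 40, d = 100, sep = 6, seed = 8) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * d), 3)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * d, sd = 1), n_per) +
      matrix(centers[k, ], n_per, d, byrow = TRUE)))
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(3 * n_per)),
    contrast_label = rep(c("a", "b", "c"), each = n_per),
    z_latent = lapply(seq_len(3 * n_per), function(i) X[i, ]))
}

test_that("UMAP fit records defaults and is reproducible per seed", {
  lat <- cluster_latents()
  em1 <- fit_umap(lat, seed = 42)
  expect_equal(em1$n_neighbors, 15)
  expect_equal(em1$min_dist, 0.1)
  expect_equal(em1$n_components, 2)
  expect_equal(em1$metric, "euclidean")
  em2 <- fit_umap(lat, seed = 42)
  expect_identical(em1$embedding, em2$embedding)
  expect_error(fit_umap(lat[1:10, ]), "at least")
})

test_that("well-separated latent clusters embed with silhouette > 0.2", {
  lat <- cluster_latents()
  em <- fit_umap(lat, seed = 42)
  emb <- transform_latents(em, lat)
  expect_gt(embedding_silhouette(emb, lat$contrast_label), 0.2)
})

test_that("transform is fit-once/transform-many and lands test points near
           their cluster", {
  lat <- cluster_latents()
  em <- fit_umap(lat, seed = 42)
  before <- em$embedding

  ## self-transform stays close relative to the embedding spread
  self <- transform_latents(em, lat)
  spread <- sqrt(sum(apply(before, 2, stats::var)))
  disp <- sqrt(rowSums((as.matrix(self[, c("umap1", "umap2")]) -
                          before)^2))
  expect_lt(mean(disp), 0.5 * spread)
  expect_identical(em$embedding, before)   # model state untouched

  ## single point transforms to a finite pair
  one <- transform_latents(em, lat[5, ])
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(unlist(one[, c("umap1", "umap2")]))))

  ## fresh draws from cluster "a" land nearest the embedded "a" centroid
  set.seed(9)
  centers <- t(vapply(split(as.data.frame(before), lat$contrast_label),
                      colMeans, numeric(2)))
  z_a <- latent_matrix(lat$z_latent[lat$contrast_label == "a"])
  new_pts <- z_a[sample(nrow(z_a), 20), ] + matrix(rnorm(20 * 100, sd = 0.5),
                                                   20)
  co <- transform_latents(em, new_pts)
  hits <- vapply(seq_len(nrow(co)), function(i) {
    d2 <- rowSums((centers - matrix(as.numeric(co[i, c("umap1", "umap2")]),
                                    3, 2, byrow = TRUE))^2)
    rownames(centers)[which.min(d2)] == "a"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("centroids are group means with the expected algebra", {
  lat <- cluster_latents(n_per = 3)
  single <- class_centroid(lat[1, ])
  expect_equal(single[["a"]], lat$z_latent[[1]])

  two <- class_centroid(lat[1:2, ])
  expect_equal(two[["a"]], (lat$z_latent[[1]] + lat$z_latent[[2]]) / 2)

  perm <- class_centroid(lat[sample(nrow(lat)), ])
  orig <- class_centroid(lat)
  expect_equal(perm[order(names(perm))], orig[order(names(orig))])

  ## linearity: centroid of a union is the weighted mean of centroids
  u <- class_centroid(mutate(lat, contrast_label = "all"))[["all"]]
  w <- Reduce(`+`, lapply(names(orig), function(k)
    sum(lat$contrast_label == k) * orig[[k]])) / nrow(lat)
  expect_equal(u, w, tolerance = 1e-12)

  expect_error(class_centroid(lat[0, ]), "empty|non-empty|zero",
               ignore.case = TRUE)
})

test_that("latent traversal interpolates between decodings", {
  st <- small_trained()
  cents <- class_centroid(st$latents)
  z_a <- cents[[1]]; z_b <- cents[[2]]

  two <- traverse_latent(st$model, z_a, z_b, steps = 2)
  expect_equal(two[[1]], decode_latent(st$model, z_a)[[1]])
  expect_equal(two[[2]], decode_latent(st$model, z_b)[[1]])

  same <- traverse_latent(st$model, z_a, z_a, steps = 4)
  expect_equal(same[[1]], same[[4]])

  frames <- traverse_latent(st$model, z_a, z_b, steps = 7)
  target <- as.numeric(decode_latent(st$model, z_b)[[1]])
  cors <- vapply(frames, function(f) cor(as.numeric(f), target),
                 numeric(1))
  expect_gt(cors[7], cors[1])
  expect_true(all(diff(cors) > -0.05))   # morphing toward the target

  expect_error(traverse_latent(st$model, z_a, z_b, steps = 1), ">= 2")
})

test_that("embedding-space points map back to nearest latent records", {
  lat <- cluster_latents(n_per = 10)
  em <- fit_umap(lat, n_neighbors = 5, seed = 1)
  emb <- transform_latents(em, lat)
  q <- as.numeric(emb[3, c("umap1", "umap2")])
  got <- nearest_latent(emb, lat, matrix(q, 1))
  expect_equal(got[[1]], lat$z_latent[[3]])
})
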