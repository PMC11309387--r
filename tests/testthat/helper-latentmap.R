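## Shared fixtures, cached per test session.  Everything is generated in
## code under fixed seeds; nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

## A pocket cohort for I/O and plumbing tests.
tiny_cohort <- function() {
  cached("tiny_cohort", simulate_cohort(
    sim_config(n_subjects = 12, shape = c(8, 8, 8),
               nidp_specs = default_nidp_specs(n_planted = 2, n_null = 3),
               seed = 11L)))
}

## A small trained autoencoder (8^3 volumes, 24 subjects, 8 epochs) shared
## by the autoencoder / embedding unit tests.
small_trained <- function() {
  cached("small_trained", {
    co <- simulate_cohort(sim_config(n_subjects = 24, shape = c(8, 8, 8),
                                     seed = 5L))
    norm <- fit_normalizer(co$scans)
    sn <- apply_normalizer(norm, co$scans)
    cfg <- ae_config(input_shape = c(8, 8, 8), epochs = 8, seed = 5L)
    model <- train_ae(build_model(cfg), sn, co$demographics)
    list(cohort = co, normalizer = norm, scans_norm = sn, model = model,
         latents = encode_scans(model, sn))
  })
}

## Slow, obviously-correct 3-D "same"-padded convolution used as the
## oracle for the compiled kernels.
r_conv3d_reference <- function(x, w, bias) {
  d <- dim(x); K <- dim(w)[1]; H <- K %/% 2
  Cin <- d[4]; B <- d[5]; Cout <- dim(w)[5]
  out <- array(0, c(d[1:3], Cout, B))
  for (b in 1:B) for (co in 1:Cout) {
    acc <- array(bias[co], d[1:3])
    for (ci in 1:Cin) for (kz in 1:K) for (ky in 1:K) for (kx in 1:K) {
      dx <- kx - H - 1; dy <- ky - H - 1; dz <- kz - H - 1
      for (z in 1:d[3]) for (y in 1:d[2]) for (xx in 1:d[1]) {
        xs <- xx + dx; ys <- y + dy; zs <- z + dz
        if (xs >= 1 && xs <= d[1] && ys >= 1 && ys <= d[2] &&
            zs >= 1 && zs <= d[3])
          acc[xx, y, z] <- acc[xx, y, z] +
            w[kx, ky, kz, ci, co] * x[xs, ys, zs, ci, b]
      }
    }
    out[, , , co, b] <- acc
  }
  out
}

expect_no_subject_overlap <- function(folds) {
  k <- attr(folds, "k")
  for (f in 0:(k - 1)) {
    test <- folds$subject_id[folds$fold == f]
    train <- folds$subject_id[folds$fold != f]
    expect_length(intersect(test, train), 0)
  }
}

## Scratch file path inside the session temp dir.
withr_local_file <- function(name) {
  d <- file.path(tempdir(), "latentmap-tests")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  file.path(d, name)
}
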