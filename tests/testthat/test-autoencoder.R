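test_that("compiled conv3d matches the reference oracle and its gradients", {
  set.seed(4)
  d <- c(5, 4, 6, 3, 2); K <- 3; Cout <- 2
  x <- array(rnorm(prod(d)), d)
  w <- array(rnorm(K^3 * d[4] * Cout), c(K, K, K, d[4], Cout))
  bias <- rnorm(Cout)
  ref <- r_conv3d_reference(x, w, bias)
  got <- array(latentmap:::cpp_conv3d_fw(as.numeric(x), dim(x),
                                         as.numeric(w), K, Cout, bias),
               dim(ref))
  expect_lt(max(abs(got - ref)), 1e-12)

  gy <- array(rnorm(length(ref)), dim(ref))
  bw <- latentmap:::cpp_conv3d_bw(as.numeric(x), dim(x), as.numeric(w),
                                  K, Cout, as.numeric(gy))
  loss <- function(xv, wv) sum(latentmap:::cpp_conv3d_fw(
    xv, dim(x), wv, K, Cout, bias) * as.numeric(gy))
  eps <- 1e-6
  for (i in sample(length(x), 4)) {
    xp <- as.numeric(x); xm <- xp; xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    fd <- (loss(xp, as.numeric(w)) - loss(xm, as.numeric(w))) / (2 * eps)
    expect_equal(bw$gx[i], fd, tolerance = 1e-5)
  }
  for (i in sample(length(w), 4)) {
    wp <- as.numeric(w); wm <- wp; wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
    fd <- (loss(as.numeric(x), wp) - loss(as.numeric(x), wm)) / (2 * eps)
    expect_equal(bw$gw[i], fd, tolerance = 1e-5)
  }
})

test_that("pooling and upsampling are exact block operations", {
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  p <- array(latentmap:::cpp_avgpool_fw(as.numeric(x), dim(x), 2L),
             c(2, 2, 2, 2, 2))
  expect_equal(p[1, 1, 1, 1, 1], mean(x[1:2, 1:2, 1:2, 1, 1]))
  expect_equal(p[2, 1, 2, 2, 1], mean(x[3:4, 1:2, 3:4, 2, 1]))
  u <- array(latentmap:::cpp_upsample_fw(as.numeric(p), dim(p), 2L), dim(x))
  expect_equal(u[1, 1, 1, 1, 1], p[1, 1, 1, 1, 1])
  expect_equal(u[4, 4, 4, 2, 2], p[2, 2, 2, 2, 2])
  ## pooling then upsampling a constant is the identity
  cst <- array(2, dim(x))
  pu <- latentmap:::cpp_upsample_fw(
    latentmap:::cpp_avgpool_fw(as.numeric(cst), dim(cst), 2L),
    c(2L, 2L, 2L, 2L, 2L), 2L)
  expect_equal(max(abs(pu - 2)), 0)
})

test_that("model construction obeys the configured architecture", {
  cfg <- ae_config(input_shape = c(8, 8, 8), seed = 2)
  m <- build_model(cfg)
  expect_equal(dim(m$params$enc_conv[[1]]$w), c(3, 3, 3, 1, 32))
  expect_equal(dim(m$params$enc_conv[[3]]$w), c(3, 3, 3, 16, 8))
  expect_equal(dim(m$params$dec_conv[[3]]$w), c(3, 3, 3, 16, 32))
  expect_equal(dim(m$params$enc_dense$w), c(100, 8))  # 1^3 * 8 after 3 pools
  ## same seed, same initial weights
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)
  expect_error(ae_config(input_shape = c(12, 8, 8)), "divisible")
})

test_that("encode and decode respect latent dimension and input shape", {
  st <- small_trained()
  lat <- st$latents
  expect_true(all(lengths(lat$z_latent) == 100))
  dec <- decode_latent(st$model, lat$z_latent[[1]])
  expect_equal(dim(dec[[1]]), c(8, 8, 8))
  zero <- decode_latent(st$model, numeric(100))
  expect_true(all(is.finite(zero[[1]])))
  expect_error(decode_latent(st$model, numeric(7)), "length 100")
  ## inference is deterministic and repeatable
  lat2 <- encode_scans(st$model, st$scans_norm)
  expect_identical(lat$z_latent[[4]], lat2$z_latent[[4]])
})

test_that("joint loss reproduces the stated formula and its edge cases", {
  ## hand-computed example: 0.5*1 + 0.5*2 + 0.5*log(2)
  l <- joint_loss(x = 0, xhat = 1, y_age = 10, age_pred = 12,
                  y_sex = 1, sex_prob = 0.5, lambda = 0.5)
  expect_equal(l$total, 0.5 * 1 + 0.5 * 2 + 0.5 * log(2),
               tolerance = 1e-12)
  expect_equal(l$total, 1.8466, tolerance = 1e-4)
  expect_equal(l$total, l$recon * 0.5 + (1 - 0.5) * (l$age + l$sex))

  ## lambda = 1: reconstruction only; supervised predictions irrelevant
  v1 <- joint_loss(0:3, 1:4, 50, 99, 1, 0.001, lambda = 1)
  v2 <- joint_loss(0:3, 1:4, 50, 12, 1, 0.999, lambda = 1)
  expect_equal(v1$total, v2$total)
  expect_equal(v1$total, mean((0:3 - 1:4)^2))

  ## perfect reconstruction and predictions drive the loss to 0
  near <- joint_loss(1:3, 1:3, 40, 40, 1, 1 - 1e-12, lambda = 0.3)
  expect_lt(near$total, 1e-10)

  expect_error(joint_loss(1, 1, 1, 1, 1, 1.2, 0.5), "outside")
})

test_that("at lambda = 1 supervised-head gradients vanish", {
  co <- tiny_cohort()
  norm <- fit_normalizer(co$scans)
  sn <- apply_normalizer(norm, co$scans)
  cfg <- ae_config(input_shape = c(8, 8, 8), lambda = 1,
                   input_noise_sd = 0, dropout_rate = 0, seed = 3)
  m <- build_model(cfg)
  vm <- latentmap:::as_voxel_matrix(sn)[["mat"]][, 1:4]
  demo <- latentmap:::match_demographics(sn[1:4, ], co$demographics)
  fw <- latentmap:::ae_forward(m$params, cfg, vm, training = FALSE)
  bw <- latentmap:::ae_backward(m$params, cfg, fw, vm, demo$age, demo$sex)
  expect_equal(max(abs(bw$grads$head_age$w)), 0)
  expect_equal(max(abs(bw$grads$head_sex$w)), 0)

  ## finite-difference confirmation on a head weight
  loss_at <- function(wval) {
    p <- m$params; p$head_age$w[1] <- wval
    fw2 <- latentmap:::ae_forward(p, cfg, vm, training = FALSE)
    bw2 <- latentmap:::ae_backward(p, cfg, fw2, vm, demo$age, demo$sex)
    bw2$total
  }
  w0 <- m$params$head_age$w[1]
  fd <- (loss_at(w0 + 1e-4) - loss_at(w0 - 1e-4)) / 2e-4
  expect_lt(abs(fd), 1e-6)
})

test_that("loss components always recompose into the total", {
  co <- tiny_cohort()
  sn <- apply_normalizer(fit_normalizer(co$scans), co$scans)
  cfg <- ae_config(input_shape = c(8, 8, 8), lambda = 0.05, seed = 9)
  m <- build_model(cfg)
  vm <- latentmap:::as_voxel_matrix(sn)[["mat"]]
  demo <- latentmap:::match_demographics(sn, co$demographics)
  set.seed(1)
  for (rep in 1:3) {
    idx <- sample(ncol(vm), 5)
    fw <- latentmap:::ae_forward(m$params, cfg, vm[, idx], training = TRUE)
    bw <- latentmap:::ae_backward(m$params, cfg, fw, vm[, idx],
                                  demo$age[idx], demo$sex[idx])
    expect_equal(bw$total,
                 0.05 * bw$recon + 0.95 * (bw$age + bw$sex),
                 tolerance = 1e-12)
  }
})

test_that("training: schedule closed form, zero-epoch identity, descent", {
  cfg <- ae_config(input_shape = c(8, 8, 8), epochs = 50, seed = 1)
  e <- c(0, 7, 49)
  expect_equal(lr_schedule(cfg, e),
               0.001 * (0.3)^(e / 50), tolerance = 1e-9)

  st <- small_trained()
  h <- st$model$history
  expect_equal(nrow(h), st$model$epochs_trained)
  expect_true(all(is.finite(h$total)))
  expect_lt(h$total[nrow(h)], h$total[1])

  co <- st$cohort
  m0 <- build_model(ae_config(input_shape = c(8, 8, 8), epochs = 0,
                              seed = 5))
  m0b <- train_ae(m0, st$scans_norm, co$demographics)
  expect_identical(m0b$params, m0$params)

  expect_error(train_ae(build_model(ae_config(c(8, 8, 8), seed = 1)),
                        st$scans_norm,
                        co$demographics[-1, ]),
               "missing demographics")
})

test_that("warm-start retraining adapts to a shifted-age cohort", {
  st <- small_trained()
  shifted <- simulate_cohort(sim_config(n_subjects = 20, shape = c(8, 8, 8),
                                        age_range = c(70, 100), seed = 77))
  norm2 <- fit_normalizer(shifted$scans)
  sn2 <- apply_normalizer(norm2, shifted$scans)

  ## zero-epoch retrain leaves weights untouched
  same <- transfer_retrain(st$model, sn2, shifted$demographics, epochs = 0)
  expect_identical(same$params, st$model$params)

  before <- encode_scans(st$model, sn2)
  mae_before <- mean(abs(before$age_pred -
                           latentmap:::match_demographics(
                             sn2, shifted$demographics)$age))
  re <- transfer_retrain(st$model, sn2, shifted$demographics, epochs = 6)
  expect_equal(re$history$lr[nrow(st$model$history) + 1], 0.0003)
  after <- encode_scans(re, sn2)
  mae_after <- mean(abs(after$age_pred -
                          latentmap:::match_demographics(
                            sn2, shifted$demographics)$age))
  expect_lt(mae_after, mae_before)
})

test_that("tidy and glance summarise the training history", {
  st <- small_trained()
  td <- tidy(st$model)
  expect_setequal(unique(td$component), c("recon", "age", "sex", "total"))
  gl <- glance(st$model)
  expect_equal(gl$epochs_trained, st$model$epochs_trained)
  expect_equal(gl$lambda, 0.05)
})
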