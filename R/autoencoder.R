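#' Autoencoder configuration
#'
#' Architecture and optimisation settings for the 3-D semi-supervised
#' denoising convolutional autoencoder. The defaults are the final
#' architecture used throughout: three encoder convolutions with 3x3x3
#' kernels and 32/16/8 filters, each followed by ReLU and average pooling
#' by 2; a 100-unit dense bottleneck; single linear (age) and sigmoid (sex)
#' supervised heads off the bottleneck; a mirrored decoder with 8/16/32
#' filters and nearest-neighbour upsampling; a linear output convolution.
#' Dropout 0.2 on every hidden layer and Gaussian input noise (sd 0.1)
#' during training. The joint loss weight `lambda` balances reconstruction
#' against the demographic heads (`lambda = 1` is a vanilla unsupervised
#' autoencoder); its default 0.05 follows the published calibration.
#'
#' @param input_shape Integer triple; each axis must be divisible by
#'   `pool_factor ^ length(encoder_filters)`.
#' @param encoder_filters Filters per encoder stage (decoder uses the
#'   reverse).
#' @param kernel_size Convolution kernel edge (odd).
#' @param pool_factor Average-pooling factor per stage.
#' @param latent_dim Bottleneck width.
#' @param dropout_rate Hidden-layer dropout probability.
#' @param input_noise_sd Sd of the Gaussian corruption added to inputs
#'   during training (denoising criterion).
#' @param lambda Reconstruction weight in `[0, 1]`; the age (MAE) and sex
#'   (binary cross-entropy) terms are weighted `1 - lambda`.
#' @param base_lr,final_lr Adam learning rate, decayed geometrically per
#'   epoch from `base_lr` towards `final_lr`.
#' @param epochs,batch_size Training schedule.
#' @param seed Seed for weight initialisation, shuffling, noise and
#'   dropout.
#' @return An `ae_config` list.
#' @export
ae_config <- function(input_shape,
                      encoder_filters = c(32, 16, 8),
                      kernel_size = 3,
                      pool_factor = 2,
                      latent_dim = 100,
                      dropout_rate = 0.2,
                      input_noise_sd = 0.1,
                      lambda = 0.05,
                      base_lr = 0.001,
                      final_lr = 0.0003,
                      epochs = 1000,
                      batch_size = 10,
                      seed = 1L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, lambda >= 0, lambda <= 1,
            latent_dim >= 1, dropout_rate >= 0, dropout_rate < 1,
            base_lr > 0, final_lr > 0, batch_size >= 1, epochs >= 0,
            kernel_size %% 2 == 1)
  down <- pool_factor^length(encoder_filters)
  if (any(input_shape %% down != 0))
    abort(sprintf(
      "input_shape must be divisible by pool_factor^%d = %d on every axis",
      length(encoder_filters), down))
  structure(list(input_shape = input_shape,
                 encoder_filters = as.integer(encoder_filters),
                 decoder_filters = rev(as.integer(encoder_filters)),
                 kernel_size = as.integer(kernel_size),
                 pool_factor = as.integer(pool_factor),
                 latent_dim = as.integer(latent_dim),
                 dropout_rate = dropout_rate,
                 input_noise_sd = input_noise_sd,
                 lambda = lambda, base_lr = base_lr, final_lr = final_lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ae_config")
}

## Spatial shape entering decoder stage 1 / leaving encoder stage 3.
ae_bottom_shape <- function(cfg) {
  cfg$input_shape %/% cfg$pool_factor^length(cfg$encoder_filters)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Build an (untrained) semi-supervised autoencoder
#'
#' Allocates all weight tensors with Glorot/Xavier uniform initialisation
#' under `cfg$seed`; the same seed always yields identical initial weights.
#'
#' @param cfg An [ae_config()].
#' @return A `trained_ae` object (zero epochs trained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "ae_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  K <- cfg$kernel_size
  k3 <- K^3
  ef <- cfg$encoder_filters
  df <- cfg$decoder_filters
  bshape <- ae_bottom_shape(cfg)
  flat <- prod(bshape) * ef[length(ef)]

  conv_layer <- function(cin, cout)
    list(w = glorot(c(K, K, K, cin, cout), k3 * cin, k3 * cout),
         b = numeric(cout))
  dense_layer <- function(nout, nin)
    list(w = glorot(c(nout, nin), nin, nout), b = numeric(nout))

  params <- list(
    enc_conv = list(conv_layer(1, ef[1]), conv_layer(ef[1], ef[2]),
                    conv_layer(ef[2], ef[3])),
    enc_dense = dense_layer(cfg$latent_dim, flat),
    head_age = dense_layer(1, cfg$latent_dim),
    head_sex = dense_layer(1, cfg$latent_dim),
    dec_dense = dense_layer(flat, cfg$latent_dim),
    dec_conv = list(conv_layer(ef[3], df[1]), conv_layer(df[1], df[2]),
                    conv_layer(df[2], df[3])),
    out_conv = conv_layer(df[3], 1))

  structure(list(params = params, config = cfg,
                 history = tibble(epoch = integer(), lr = numeric(),
                                  recon = numeric(), age = numeric(),
                                  sex = numeric(), total = numeric()),
                 epochs_trained = 0L),
            class = "trained_ae")
}

#' @export
print.trained_ae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<trained_ae> input %s, filters %s, latent %d, lambda %.3g; %d epochs\n",
    paste(cfg$input_shape, collapse = "x"),
    paste(cfg$encoder_filters, collapse = "/"), cfg$latent_dim,
    cfg$lambda, x$epochs_trained))
  invisible(x)
}

## ---- low-level layer wrappers over the compiled kernels -------------------

conv_fw <- function(x, dims, layer, K) {
  cpp_conv3d_fw(x, as.integer(dims), as.numeric(layer$w), K,
                length(layer$b), layer$b)
}

conv_bw <- function(x, dims, layer, K, gy) {
  cpp_conv3d_bw(x, as.integer(dims), as.numeric(layer$w), K,
                length(layer$b), gy)
}

relu <- function(x) x * (x > 0)

drop_mask <- function(len, rate, training) {
  if (!training || rate <= 0) return(NULL)
  (runif(len) >= rate) / (1 - rate)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

## Forward pass over a batch. `xmat` is voxels x B (normalized space).
## Returns activations needed for the backward pass.
ae_forward <- function(params, cfg, xmat, training = FALSE) {
  K <- cfg$kernel_size
  f <- cfg$pool_factor
  B <- ncol(xmat)
  sh <- cfg$input_shape
  ef <- cfg$encoder_filters
  df <- cfg$decoder_filters
  d0 <- c(sh, 1L, B)

  x0 <- as.numeric(xmat)
  if (training && cfg$input_noise_sd > 0)
    x0 <- x0 + rnorm(length(x0), sd = cfg$input_noise_sd)

  env <- list(x0 = x0, B = B)
  dims <- d0
  a <- x0
  for (i in 1:3) {
    ci <- conv_fw(a, dims, params$enc_conv[[i]], K)
    cdim <- c(dims[1:3], ef[i], B)
    ri <- relu(ci)
    mi <- drop_mask(length(ri), cfg$dropout_rate, training)
    di <- apply_mask(ri, mi)
    pi <- cpp_avgpool_fw(di, as.integer(cdim), f)
    env[[paste0("c", i)]] <- ci
    env[[paste0("m", i)]] <- mi
    env[[paste0("cdim", i)]] <- cdim
    a <- pi
    dims <- c(cdim[1:3] %/% f, ef[i], B)
    env[[paste0("pdim", i)]] <- dims
    env[[paste0("p", i)]] <- pi
  }
  flat <- prod(dims[1:4])
  fmat <- matrix(a, flat, B)
  zpre <- params$enc_dense$w %*% fmat + params$enc_dense$b
  z <- relu(zpre)
  mz <- drop_mask(length(z), cfg$dropout_rate, training)
  zd <- apply_mask(z, mz)

  age_pred <- drop(params$head_age$w %*% zd + params$head_age$b)
  sex_logit <- drop(params$head_sex$w %*% zd + params$head_sex$b)

  gpre <- params$dec_dense$w %*% zd + params$dec_dense$b
  g <- relu(gpre)
  mg <- drop_mask(length(g), cfg$dropout_rate, training)
  gd <- apply_mask(g, mg)

  env <- c(env, list(fmat = fmat, zpre = zpre, z = z, mz = mz, zd = zd,
                     age_pred = age_pred, sex_logit = sex_logit,
                     gpre = gpre, mg = mg, gd = gd, flat = flat))

  bshape <- ae_bottom_shape(cfg)
  a <- as.numeric(gd)
  dims <- c(bshape, ef[3], B)
  for (i in 1:3) {
    ci <- conv_fw(a, dims, params$dec_conv[[i]], K)
    cdim <- c(dims[1:3], df[i], B)
    ri <- relu(ci)
    mi <- drop_mask(length(ri), cfg$dropout_rate, training)
    di <- apply_mask(ri, mi)
    ui <- cpp_upsample_fw(di, as.integer(cdim), f)
    env[[paste0("dc", i)]] <- ci
    env[[paste0("dm", i)]] <- mi
    env[[paste0("ddim", i)]] <- cdim
    env[[paste0("u", i)]] <- ui
    a <- ui
    dims <- c(cdim[1:3] * f, df[i], B)
    env[[paste0("udim", i)]] <- dims
  }
  xhat <- conv_fw(a, dims, params$out_conv, K)
  env$xhat <- matrix(xhat, prod(sh), B)
  env$udim_last <- dims
  env
}

## Loss gradients and backward pass; returns per-tensor gradients matching
## the structure of `params`, plus the scalar loss components.
ae_backward <- function(params, cfg, fw, x_clean, age, sex) {
  K <- cfg$kernel_size
  f <- cfg$pool_factor
  B <- fw$B
  lam <- cfg$lambda
  nvox <- nrow(fw$xhat)

  resid <- fw$xhat - x_clean
  recon <- mean(resid^2)
  age_err <- fw$age_pred - age
  mae <- mean(abs(age_err))
  sp <- 1 / (1 + exp(-fw$sex_logit))
  bce <- mean(log1p(exp(-abs(fw$sex_logit))) +
                pmax(fw$sex_logit, 0) - sex * fw$sex_logit)
  total <- lam * recon + (1 - lam) * (mae + bce)

  g <- list(enc_conv = vector("list", 3), dec_conv = vector("list", 3))

  ## output conv
  g_xhat <- as.numeric(lam * 2 * resid / (nvox * B))
  bwo <- conv_bw(fw$u3, fw$udim_last, params$out_conv, K, g_xhat)
  g$out_conv <- list(w = array(bwo$gw, dim(params$out_conv$w)), b = bwo$gb)
  ga <- bwo$gx

  ## decoder conv stages, reversed
  for (i in 3:1) {
    cdim <- fw[[paste0("ddim", i)]]
    ga <- cpp_upsample_bw(ga, as.integer(cdim), f)
    ga <- apply_mask(ga, fw[[paste0("dm", i)]])
    ga <- ga * (fw[[paste0("dc", i)]] > 0)
    indim <- if (i == 1) c(ae_bottom_shape(cfg), cfg$encoder_filters[3], B)
             else fw[[paste0("udim", i - 1)]]
    src <- if (i == 1) as.numeric(fw$gd) else fw[[paste0("u", i - 1)]]
    bw <- conv_bw(src, indim, params$dec_conv[[i]], K, ga)
    g$dec_conv[[i]] <- list(w = array(bw$gw, dim(params$dec_conv[[i]]$w)),
                            b = bw$gb)
    ga <- bw$gx
  }

  ## dense decoder
  g_gd <- matrix(ga, fw$flat, B)
  g_gpre <- apply_mask(g_gd, fw$mg) * (fw$gpre > 0)
  g$dec_dense <- list(w = g_gpre %*% t(fw$zd), b = rowSums(g_gpre))
  g_zd <- t(params$dec_dense$w) %*% g_gpre

  ## supervised heads
  g_age <- (1 - lam) * sign(age_err) / B
  g_sex <- (1 - lam) * (sp - sex) / B
  g$head_age <- list(w = matrix(g_age, 1) %*% t(fw$zd), b = sum(g_age))
  g$head_sex <- list(w = matrix(g_sex, 1) %*% t(fw$zd), b = sum(g_sex))
  g_zd <- g_zd + t(params$head_age$w) %*% matrix(g_age, 1) +
    t(params$head_sex$w) %*% matrix(g_sex, 1)

  ## bottleneck
  g_zpre <- apply_mask(g_zd, fw$mz) * (fw$zpre > 0)
  g$enc_dense <- list(w = g_zpre %*% t(fw$fmat), b = rowSums(g_zpre))
  ga <- as.numeric(t(params$enc_dense$w) %*% g_zpre)

  ## encoder conv stages, reversed
  for (i in 3:1) {
    cdim <- fw[[paste0("cdim", i)]]
    ga <- cpp_avgpool_bw(ga, as.integer(cdim), f)
    ga <- apply_mask(ga, fw[[paste0("m", i)]])
    ga <- ga * (fw[[paste0("c", i)]] > 0)
    indim <- if (i == 1) c(cfg$input_shape, 1L, B)
             else fw[[paste0("pdim", i - 1)]]
    src <- if (i == 1) fw$x0 else fw[[paste0("p", i - 1)]]
    bw <- conv_bw(src, indim, params$enc_conv[[i]], K, ga)
    g$enc_conv[[i]] <- list(w = array(bw$gw, dim(params$enc_conv[[i]]$w)),
                            b = bw$gb)
    ga <- bw$gx
  }

  list(grads = g, recon = recon, age = mae, sex = bce, total = total)
}

#' Joint semi-supervised loss
#'
#' `total = lambda * MSE(x, xhat) + (1 - lambda) * MAE(y_age, age_pred) +
#' (1 - lambda) * BCE(y_sex, sex_prob)`, with age in raw years and sex
#' probabilities in (0, 1). At `lambda = 1` the supervised terms vanish and
#' the criterion reduces to a vanilla autoencoder reconstruction loss.
#'
#' @param x,xhat Numeric arrays/vectors of equal length (original and
#'   reconstructed volumes).
#' @param y_age,age_pred True and predicted ages (years).
#' @param y_sex,sex_prob True sex codes in `{0, 1}` and predicted
#'   probabilities in the open interval (0, 1).
#' @param lambda Reconstruction weight in `[0, 1]`.
#' @return List with components `total`, `recon`, `age`, `sex`.
#' @export
joint_loss <- function(x, xhat, y_age, age_pred, y_sex, sex_prob, lambda) {
  stopifnot(length(x) == length(xhat), lambda >= 0, lambda <= 1)
  if (any(sex_prob <= 0 | sex_prob >= 1))
    abort("sex probabilities outside (0, 1): binary cross-entropy undefined")
  recon <- mean((as.numeric(x) - as.numeric(xhat))^2)
  age <- mean(abs(y_age - age_pred))
  sex <- mean(-y_sex * log(sex_prob) - (1 - y_sex) * log(1 - sex_prob))
  list(total = lambda * recon + (1 - lambda) * (age + sex),
       recon = recon, age = age, sex = sex)
}

#' Per-epoch learning rate of the geometric decay schedule
#'
#' `lr(e) = base_lr * (final_lr / base_lr)^(e / epochs)` for 0-based epoch
#' index `e`, so training starts at `base_lr` and approaches `final_lr`.
#'
#' @param cfg An [ae_config()].
#' @param epoch 0-based epoch index.
#' @export
lr_schedule <- function(cfg, epoch) {
  cfg$base_lr * (cfg$final_lr / cfg$base_lr)^(epoch / max(cfg$epochs, 1))
}

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = c("numeric", "array", "matrix"))
}

## One Adam update, walking the nested parameter list.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          r <- upd(p[[i]], g[[i]], s[[i]])
          out_p[[i]] <- r$p; out_s[[i]] <- r$s
        }
      }
      list(p = out_p, s = out_s)
    } else {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
    }
  }
  upd(params, grads, state)
}

## Align demographics rows to a scan table; errors on missing subjects.
match_demographics <- function(scans, demographics) {
  validate_demographics(demographics)
  idx <- match(scans$subject_id, demographics$subject_id)
  if (anyNA(idx))
    abort(paste0("missing demographics for subject(s): ",
                 paste(unique(scans$subject_id[is.na(idx)]),
                       collapse = ", ")))
  demographics[idx, ]
}

#' Train the semi-supervised autoencoder
#'
#' Mini-batch Adam with geometric per-epoch learning-rate decay
#' ([lr_schedule()]). Input noise and dropout are active only during
#' training; batches pool all contrast labels. Scans are expected in
#' normalized space ([apply_normalizer()]).
#'
#' @param model A `trained_ae` from [build_model()] (or a previous
#'   training run -- training continues from the current weights).
#' @param scans Scan tibble with a `volume` list-column.
#' @param demographics Tibble with `subject_id`, `age`, `sex` covering
#'   every scanned subject.
#' @param epochs,base_lr,final_lr,batch_size Optional overrides of the
#'   model's config for this run.
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return The model with updated weights and per-epoch `history`
#'   (reconstruction MSE, age MAE, sex BCE, total, learning rate).
#' @export
train_ae <- function(model, scans, demographics, epochs = NULL,
                     base_lr = NULL, final_lr = NULL, batch_size = NULL,
                     verbose = 0) {
  stopifnot(inherits(model, "trained_ae"))
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(base_lr)) cfg$base_lr <- base_lr
  if (!is.null(final_lr)) cfg$final_lr <- final_lr
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  if (cfg$epochs == 0L) return(model)

  demo <- match_demographics(scans, demographics)
  vm <- as_voxel_matrix(scans)
  if (!identical(vm$shape, cfg$input_shape))
    abort("scan shape does not match the model's input_shape")
  n <- ncol(vm$mat)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed + model$epochs_trained)

  params <- model$params
  ## Calibrate the raw-years age head before the first epoch: starting the
  ## output bias at the training-mean age means the head only has to learn
  ## deviations, not the age scale itself.
  if (model$epochs_trained == 0L && params$head_age$b == 0)
    params$head_age$b <- mean(demo$age)
  state <- adam_init(params)
  t_step <- 0L
  hist <- vector("list", cfg$epochs)

  for (e in seq_len(cfg$epochs)) {
    lr <- lr_schedule(cfg, e - 1L)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    comp <- matrix(0, length(starts), 4)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
      xb <- vm$mat[, idx, drop = FALSE]
      fw <- ae_forward(params, cfg, xb, training = TRUE)
      bw <- ae_backward(params, cfg, fw, xb, demo$age[idx], demo$sex[idx])
      if (!is.finite(bw$total))
        abort(sprintf("non-finite loss at epoch %d (batch %d)", e, bi))
      t_step <- t_step + 1L
      r <- adam_step(params, bw$grads, state, lr, t_step)
      params <- r$p; state <- r$s
      comp[bi, ] <- c(bw$recon, bw$age, bw$sex, bw$total)
    }
    m <- colMeans(comp)
    hist[[e]] <- tibble(epoch = model$epochs_trained + e, lr = lr,
                        recon = m[1], age = m[2], sex = m[3], total = m[4])
    if (verbose > 0 && (e %% verbose == 0 || e == 1))
      inform(sprintf("epoch %d/%d  lr %.2g  total %.4f (recon %.4f)",
                     e, cfg$epochs, lr, m[4], m[1]))
  }
  model$params <- params
  model$history <- bind_rows(model$history, bind_rows(hist))
  model$epochs_trained <- model$epochs_trained + cfg$epochs
  model$config <- cfg
  model
}

#' Warm-start retraining on a second cohort
#'
#' Re-estimates *all* weights starting from the source model (no layers
#' are frozen), with the base learning rate reduced to 0.0003 by default
#' to limit drift from the already-learned features. The new cohort should
#' be normalized with its own cohort normalizer.
#'
#' @inheritParams train_ae
#' @param base_lr Warm-start base learning rate (default 0.0003).
#' @export
transfer_retrain <- function(model, scans, demographics, epochs = NULL,
                             base_lr = 0.0003, final_lr = NULL,
                             verbose = 0) {
  stopifnot(inherits(model, "trained_ae"))
  if (is.null(final_lr)) final_lr <- min(base_lr, model$config$final_lr)
  train_ae(model, scans, demographics, epochs = epochs, base_lr = base_lr,
           final_lr = final_lr, verbose = verbose)
}

#' Encode scans to latent records
#'
#' Deterministic inference pass (no noise, no dropout): each scan yields
#' its latent vector plus the supervised-head predictions.
#'
#' @param model A trained `trained_ae`.
#' @param scans Scan tibble in normalized space.
#' @return Tibble with `subject_id`, `contrast_label`, `age_pred`,
#'   `sex_prob` and a `z_latent` list-column of length-`latent_dim`
#'   vectors.
#' @export
encode_scans <- function(model, scans) {
  stopifnot(inherits(model, "trained_ae"))
  cfg <- model$config
  vm <- as_voxel_matrix(scans)
  if (!identical(vm$shape, cfg$input_shape))
    abort("scan shape does not match the model's input_shape")
  n <- ncol(vm$mat)
  zs <- matrix(0, cfg$latent_dim, n)
  age <- numeric(n); sexp <- numeric(n)
  step <- 64L
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(s + step - 1L, n)
    fw <- ae_forward(model$params, cfg, vm$mat[, idx, drop = FALSE],
                     training = FALSE)
    zs[, idx] <- fw$z
    age[idx] <- fw$age_pred
    sexp[idx] <- 1 / (1 + exp(-fw$sex_logit))
  }
  tibble(subject_id = scans$subject_id,
         contrast_label = scans$contrast_label,
         age_pred = age, sex_prob = sexp,
         z_latent = lapply(seq_len(n), function(i) zs[, i]))
}

#' Decode latent vectors to volumes (normalized space)
#'
#' @param model A trained `trained_ae`.
#' @param z A numeric vector of length `latent_dim`, a matrix with
#'   `latent_dim` columns (one row per vector), or a list of vectors.
#' @return List of 3-D arrays in normalized space; un-normalize with
#'   [invert_normalizer()].
#' @export
decode_latent <- function(model, z) {
  stopifnot(inherits(model, "trained_ae"))
  cfg <- model$config
  zm <- if (is.matrix(z)) t(z)
        else if (is.list(z)) do.call(cbind, z)
        else matrix(z, ncol = 1)
  if (nrow(zm) != cfg$latent_dim)
    abort(sprintf("latent vectors must have length %d", cfg$latent_dim))
  p <- model$params
  B <- ncol(zm)
  gd <- relu(p$dec_dense$w %*% zm + p$dec_dense$b)
  a <- as.numeric(gd)
  dims <- c(ae_bottom_shape(cfg), cfg$encoder_filters[3], B)
  for (i in 1:3) {
    ci <- relu(conv_fw(a, dims, p$dec_conv[[i]], cfg$kernel_size))
    cdim <- c(dims[1:3], cfg$decoder_filters[i], B)
    a <- cpp_upsample_fw(ci, as.integer(cdim), cfg$pool_factor)
    dims <- c(cdim[1:3] * cfg$pool_factor, cfg$decoder_filters[i], B)
  }
  xhat <- conv_fw(a, dims, p$out_conv, cfg$kernel_size)
  xm <- matrix(xhat, prod(cfg$input_shape), B)
  lapply(seq_len(B), function(i) array(xm[, i], cfg$input_shape))
}

## Helper used in several places: latent list-column -> matrix (n x d).
latent_matrix <- function(latents) {
  if (is_tibble(latents)) latents <- latents$z_latent
  do.call(rbind, latents)
}

#' @method tidy trained_ae
#' @export
tidy.trained_ae <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("recon", "age", "sex", "total"),
                      names_to = "component", values_to = "loss")
}

#' @method glance trained_ae
#' @export
glance.trained_ae <- function(x, ...) {
  h <- x$history
  last <- if (nrow(h)) h[nrow(h), ] else
    tibble(recon = NA_real_, age = NA_real_, sex = NA_real_,
           total = NA_real_)
  tibble(epochs_trained = x$epochs_trained,
         latent_dim = x$config$latent_dim, lambda = x$config$lambda,
         final_recon = last$recon, final_age_mae = last$age,
         final_sex_bce = last$sex, final_total = last$total)
}

#' @method autoplot trained_ae
#' @export
autoplot.trained_ae <- function(object, ...) {
  ggplot(tidy.trained_ae(object),
         aes(x = .data$epoch, y = .data$loss,
             colour = .data$component)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL,
         title = "Training history") +
    theme_minimal()
}
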