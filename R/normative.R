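#' Sinh-arcsinh (SHASH) transforms
#'
#' `shash_forward()` maps a SHASH variate to a standard-normal variate,
#' `z = sinh(delta * asinh(y) - epsilon)`; `shash_inverse()` is its exact
#' inverse `y = sinh((asinh(z) + epsilon) / delta)`. Both are bijective
#' and strictly increasing for `delta > 0`. `epsilon` controls skewness
#' and `delta` tail weight; `(epsilon, delta) = (0, 1)` is the identity,
#' under which the variate is standard normal.
#'
#' @param y,z Numeric vectors.
#' @param epsilon Skewness parameter (real).
#' @param delta Tail-weight parameter (> 0).
#' @return Numeric vector of the same length.
#' @export
shash_forward <- function(y, epsilon, delta) {
  if (any(delta <= 0)) abort("`delta` must be > 0")
  sinh(delta * asinh(y) - epsilon)
}

#' @rdname shash_forward
#' @export
shash_inverse <- function(z, epsilon, delta) {
  if (any(delta <= 0)) abort("`delta` must be > 0")
  sinh((asinh(z) + epsilon) / delta)
}

#' Mean and variance of the (unstandardized) SHASH distribution
#'
#' Analytic moments of `Y = sinh((asinh(Z) + epsilon) / delta)` with
#' `Z ~ N(0, 1)`, via the modified-Bessel-function expressions
#' `E[Y] = sinh(epsilon / delta) * P(1 / delta)` and
#' `E[Y^2] = (cosh(2 epsilon / delta) * P(2 / delta) - 1) / 2`, where
#' `P(q) = exp(1/4) / sqrt(8 pi) * (K((q + 1) / 2, 1/4) +
#' K((q - 1) / 2, 1/4))`. These are used to centre and scale the SHASH
#' likelihood so that its location and scale parameters are the mean and
#' standard deviation.
#'
#' @inheritParams shash_forward
#' @return List with elements `mean` and `variance`.
#' @export
shash_moments <- function(epsilon, delta) {
  if (delta <= 0) abort("`delta` must be > 0")
  Pq <- function(q) {
    exp(0.25) / sqrt(8 * pi) *
      (besselK(0.25, (q + 1) / 2) + besselK(0.25, (q - 1) / 2))
  }
  m <- sinh(epsilon / delta) * Pq(1 / delta)
  e2 <- (cosh(2 * epsilon / delta) * Pq(2 / delta) - 1) / 2
  list(mean = m, variance = e2 - m^2)
}

#' Normative model configuration
#'
#' Settings for the hierarchical Bayesian normative regression of one
#' embedding component on age, with a grouping ("batch") variable whose
#' coefficients are tied by shared hyperpriors. The location follows a
#' B-spline in age (so both linear and non-linear age trends are removed),
#' the scale is linear in age under a softplus link (heteroskedasticity),
#' and the likelihood is either Gaussian or a centred-and-scaled SHASH
#' distribution with global skewness and tail-weight parameters.
#'
#' @param likelihood `"shash"` (default) or `"gaussian"` (fixes
#'   `epsilon = 0`, `delta = 1`).
#' @param spline_degree B-spline degree for the age effect (default cubic).
#' @param n_knots Number of interior knots placed at age quantiles.
#' @param draws Posterior draws kept per chain (after warm-up).
#' @param tune Warm-up iterations discarded per chain.
#' @param chains Number of sequential chains.
#' @param target_accept Kept for API compatibility with gradient-based
#'   samplers; the univariate slice sampler used here is rejection-free
#'   and does not consume it.
#' @param seed Integer seed; identical config and data give identical
#'   posterior summaries.
#' @export
normative_config <- function(likelihood = c("shash", "gaussian"),
                             spline_degree = 3, n_knots = 5,
                             draws = 1000, tune = 1000, chains = 2,
                             target_accept = 0.9, seed = 1L) {
  likelihood <- match.arg(likelihood)
  stopifnot(draws >= 1, tune >= 0, chains >= 1, spline_degree >= 1,
            n_knots >= 0)
  structure(list(likelihood = likelihood,
                 spline_degree = as.integer(spline_degree),
                 n_knots = as.integer(n_knots),
                 draws = as.integer(draws), tune = as.integer(tune),
                 chains = as.integer(chains),
                 target_accept = target_accept, seed = as.integer(seed)),
            class = "normative_config")
}

## ---- design matrices -------------------------------------------------------

make_basis <- function(age, degree, n_knots) {
  if (length(unique(age)) < 2) abort("need more than one unique age value")
  bounds <- range(age)
  knots <- if (n_knots > 0)
    as.numeric(quantile(age, probs = seq_len(n_knots) / (n_knots + 1)))
  else numeric(0)
  B <- splines::bs(age, knots = knots, degree = degree,
                   Boundary.knots = bounds)
  ctr <- colMeans(B)
  scl <- apply(B, 2, sd)
  scl[scl < 1e-8] <- 1
  list(degree = degree, knots = knots, bounds = bounds, center = ctr,
       scale = scl)
}

eval_basis <- function(basis, age) {
  eps <- 1e-8 * max(1, diff(basis$bounds))
  if (any(age < basis$bounds[1] - eps | age > basis$bounds[2] + eps))
    abort(sprintf(
      "age outside the spline support [%.3g, %.3g]; no extrapolation",
      basis$bounds[1], basis$bounds[2]))
  age <- pmin(pmax(age, basis$bounds[1]), basis$bounds[2])
  B <- splines::bs(age, knots = basis$knots, degree = basis$degree,
                   Boundary.knots = basis$bounds)
  B <- sweep(sweep(B, 2, basis$center), 2, basis$scale, "/")
  cbind(1, B)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Standardized-scale log-likelihood of one batch.
## th: list(beta = p-vector, g0, g1, eps, delta); d: list(X, y, a).
ll_shash_batch <- function(th, d, mom) {
  mu <- drop(d$X %*% th$beta)
  sigma <- softplus(th$g0 + th$g1 * d$a) + 1e-6
  sv <- sqrt(mom$variance)
  S <- (d$y - mu) / sigma * sv + mom$mean
  r <- th$delta * asinh(S) - th$eps
  z <- sinh(r)
  ## log(cosh(r)) = 0.5 * log1p(sinh(r)^2), saving one transcendental
  sum(-0.5 * z^2 - 0.918938533204672870 + # log(sqrt(2*pi))
        log(th$delta) + 0.5 * log1p(z^2) - 0.5 * log1p(S^2) +
        0.5 * log(mom$variance) - log(sigma))
}

ll_gauss_batch <- function(th, d) {
  mu <- drop(d$X %*% th$beta)
  sigma <- softplus(th$g0 + th$g1 * d$a) + 1e-6
  r <- (d$y - mu) / sigma
  sum(-0.5 * r * r - log(sigma)) - 0.918938533204672870 * length(d$y)
}

## Univariate slice sampler with stepping out (Neal 2003).
slice1 <- function(x0, f, w, fx0 = NULL, lower = -Inf, upper = Inf) {
  if (is.null(fx0)) fx0 <- f(x0)
  if (!is.finite(fx0)) abort("slice sampler started at a -Inf point")
  y <- fx0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  for (i in 1:50) { if (L <= lower || f(L) <= y) break; L <- L - w }
  for (i in 1:50) { if (R >= upper || f(R) <= y) break; R <- R + w }
  L <- max(L, lower); R <- min(R, upper)
  for (i in 1:200) {
    x1 <- runif(1, L, R)
    if (f(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

split_rhat <- function(chains_mat) {
  ## chains_mat: list of draws x params matrices
  halves <- list()
  for (m in chains_mat) {
    n <- nrow(m); h <- n %/% 2
    halves <- c(halves, list(m[1:h, , drop = FALSE],
                             m[(h + 1):(2 * h), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(pmax((n - 1) / n + B / (W * n), 0))
}

#' Fit the hierarchical Bayesian normative model
#'
#' Samples the posterior of `y ~ SHASHb(mu_b(age), sigma_b(age), epsilon,
#' delta)` where `mu_b` follows a B-spline in age with batch-specific
#' coefficients drawn from shared hyperpriors, `sigma_b` is linear in
#' (standardized) age under a softplus link, and the global skewness
#' `epsilon` and tail weight `delta` shape the centred-and-scaled SHASH
#' likelihood (see [shash_moments()]). With `likelihood = "gaussian"` the
#' shape parameters are fixed at the identity and the likelihood is
#' normal. Sampling is by univariate slice sampling within Gibbs; the
#' response and design are standardized internally and results are
#' reported in the original units.
#'
#' @param y Numeric response (one embedding component per scan).
#' @param age Age in years per observation.
#' @param batch Batch labels (e.g. sex codes); coefficients are tied
#'   across batches by shared hyperpriors.
#' @param cfg A [normative_config()].
#' @return A `normative_fit` carrying posterior draws, plug-in posterior
#'   means, the spline basis, standardization constants and split-R-hat
#'   convergence diagnostics (a warning is raised if any exceeds 1.05).
#' @export
fit_hbr <- function(y, age, batch, cfg = normative_config()) {
  stopifnot(inherits(cfg, "normative_config"))
  if (!all(is.finite(y)) || !all(is.finite(age)))
    abort("non-finite values in y or age")
  stopifnot(length(y) == length(age), length(y) == length(batch))
  batch <- as.character(batch)
  levels <- sort(unique(batch))
  L <- length(levels)
  tab <- table(batch)
  if (any(tab < 50))
    warn(sprintf("fewer than 50 observations in batch(es): %s",
                 paste(names(tab)[tab < 50], collapse = ", ")))

  y_c <- mean(y); y_s <- sd(y); if (y_s < 1e-12) abort("constant response")
  ys <- (y - y_c) / y_s
  a_c <- mean(age); a_s <- sd(age); if (a_s < 1e-12) a_s <- 1
  basis <- make_basis(age, cfg$spline_degree, cfg$n_knots)
  X <- eval_basis(basis, age)
  p <- ncol(X)
  shash <- cfg$likelihood == "shash"

  dat <- lapply(levels, function(l) {
    i <- batch == l
    list(X = X[i, , drop = FALSE], y = ys[i], a = (age[i] - a_c) / a_s)
  })

  ## parameter bookkeeping ---------------------------------------------------
  nm <- c(as.vector(outer(seq_len(p), seq_len(L),
                          function(j, l) sprintf("beta[%d,%d]", l, j))),
          as.vector(outer(1:2, seq_len(L),
                          function(k, l) sprintf("gamma[%d,%d]", l, k))),
          if (shash) c("epsilon", "log_delta"),
          sprintf("mu_beta[%d]", seq_len(p)),
          sprintf("log_tau_beta[%d]", seq_len(p)),
          sprintf("mu_gamma[%d]", 1:2), sprintf("log_tau_gamma[%d]", 1:2))
  npar <- length(nm)
  bidx <- function(l) (l - 1) * p + seq_len(p)
  gidx <- function(l) L * p + (l - 1) * 2 + 1:2
  sidx <- if (shash) L * p + 2 * L + 1:2 else integer(0)
  h0 <- L * p + 2 * L + length(sidx)
  mb_i <- h0 + seq_len(p); tb_i <- h0 + p + seq_len(p)
  mg_i <- h0 + 2 * p + 1:2; tg_i <- h0 + 2 * p + 2 + 1:2

  ## per-parameter classification so each slice update only evaluates the
  ## prior terms that involve the updated coordinate
  ptype <- character(npar); pl <- integer(npar); pj <- integer(npar)
  for (l in seq_len(L)) {
    ptype[bidx(l)] <- "beta"; pl[bidx(l)] <- l; pj[bidx(l)] <- seq_len(p)
    ptype[gidx(l)] <- "gamma"; pl[gidx(l)] <- l; pj[gidx(l)] <- 1:2
  }
  if (shash) ptype[sidx] <- c("epsilon", "log_delta")
  ptype[mb_i] <- "mu_beta"; pj[mb_i] <- seq_len(p)
  ptype[tb_i] <- "tau_beta"; pj[tb_i] <- seq_len(p)
  ptype[mg_i] <- "mu_gamma"; pj[mg_i] <- 1:2
  ptype[tg_i] <- "tau_gamma"; pj[tg_i] <- 1:2

  ldn <- function(x, m, s) -0.5 * ((x - m) / s)^2 - log(s)
  prior_term <- function(i, x, th) {
    j <- pj[i]
    switch(ptype[i],
      beta = ldn(x, th[mb_i[j]], exp(th[tb_i[j]])),
      gamma = ldn(x, th[mg_i[j]], exp(th[tg_i[j]])),
      epsilon = ldn(x, 0, 1),
      log_delta = ldn(x, 0, 0.5),
      mu_beta = ldn(x, 0, 5) +
        sum(ldn(th[bidx_flat[[j]]], x, exp(th[tb_i[j]]))),
      tau_beta = -log1p(exp(2 * x)) + x +
        sum(ldn(th[bidx_flat[[j]]], th[mb_i[j]], exp(x))),
      mu_gamma = ldn(x, 0, 2) +
        sum(ldn(th[gidx_flat[[j]]], x, exp(th[tg_i[j]]))),
      tau_gamma = -log1p(exp(2 * x)) + x +
        sum(ldn(th[gidx_flat[[j]]], th[mg_i[j]], exp(x))))
  }
  bidx_flat <- lapply(seq_len(p), function(j)
    vapply(seq_len(L), function(l) as.integer(bidx(l)[j]), integer(1)))
  gidx_flat <- lapply(1:2, function(k)
    vapply(seq_len(L), function(l) as.integer(gidx(l)[k]), integer(1)))

  llik_l <- function(th, l) {
    bt <- list(beta = th[bidx(l)], g0 = th[gidx(l)][1],
               g1 = th[gidx(l)][2],
               eps = if (shash) th[sidx[1]] else 0,
               delta = if (shash) exp(th[sidx[2]]) else 1)
    if (shash) {
      mom <- shash_moments(bt$eps, bt$delta)
      if (!is.finite(mom$variance) || mom$variance <= 0) return(-Inf)
      ll_shash_batch(bt, dat[[l]], mom)
    } else ll_gauss_batch(bt, dat[[l]])
  }

  ## initial values from per-batch ridge least squares -----------------------
  init_theta <- function(jit) {
    th <- numeric(npar); names(th) <- nm
    for (l in seq_len(L)) {
      d <- dat[[l]]
      b <- solve(crossprod(d$X) + diag(1e-6, p), crossprod(d$X, d$y))
      th[bidx(l)] <- b
      rs <- sd(d$y - drop(d$X %*% b))
      th[gidx(l)] <- c(log(expm1(max(rs, 0.05))), 0)
    }
    th[mb_i] <- rowMeans(matrix(th[seq_len(L * p)], p))
    th[tb_i] <- log(0.3); th[mg_i] <- c(mean(th[L * p + 2 * (seq_len(L)) - 1]), 0)
    th[tg_i] <- log(0.3)
    th + rnorm(npar, 0, jit)
  }

  affected <- integer(npar)            # 0 = prior-only, -1 = all batches
  for (l in seq_len(L)) { affected[bidx(l)] <- l; affected[gidx(l)] <- l }
  if (shash) affected[sidx] <- -1L

  widths <- rep(0.25, npar)
  widths[c(mb_i, tb_i, mg_i, tg_i)] <- 0.5

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  total_iter <- cfg$tune + cfg$draws
  chains_out <- vector("list", cfg$chains)

  for (ch in seq_len(cfg$chains)) {
    th <- init_theta(jit = 0.05 * (ch - 1))
    ll <- vapply(seq_len(L), function(l) llik_l(th, l), numeric(1))
    if (!all(is.finite(ll))) {
      th <- init_theta(0)
      ll <- vapply(seq_len(L), function(l) llik_l(th, l), numeric(1))
    }
    keep <- matrix(NA_real_, cfg$draws, npar, dimnames = list(NULL, nm))
    wbuf <- if (cfg$tune > 0) matrix(NA_real_, cfg$tune, npar) else NULL
    w_ch <- widths
    for (it in seq_len(total_iter)) {
      for (i in seq_len(npar)) {
        a <- affected[i]
        rest <- if (a > 0) sum(ll[-a]) else 0
        f <- function(x) {
          th2 <- th; th2[i] <- x
          lv <- if (a > 0) llik_l(th2, a)
                else if (a < 0) sum(vapply(seq_len(L), function(l)
                  llik_l(th2, l), numeric(1)))
                else 0
          rest + lv + prior_term(i, x, th2)
        }
        fx0 <- rest + (if (a > 0) ll[a] else if (a < 0) sum(ll) else 0) +
          prior_term(i, th[i], th)
        x1 <- slice1(th[i], f, w_ch[i], fx0 = fx0)
        if (x1 != th[i]) {
          th[i] <- x1
          if (a > 0) ll[a] <- llik_l(th, a)
          else if (a < 0) ll <- vapply(seq_len(L), function(l)
            llik_l(th, l), numeric(1))
        }
      }
      if (it <= cfg$tune) {
        wbuf[it, ] <- th
        ## adapt slice widths to the warm-up posterior spread
        if (it == cfg$tune %/% 2 || it == cfg$tune) {
          half <- wbuf[max(1, it - 200):it, , drop = FALSE]
          w_ch <- pmax(2.5 * apply(half, 2, sd), 0.02)
        }
      } else {
        keep[it - cfg$tune, ] <- th
      }
    }
    chains_out[[ch]] <- keep
  }

  all_draws <- do.call(rbind, chains_out)
  pm <- colMeans(all_draws)
  rhat <- if (cfg$chains >= 1 && cfg$draws >= 4) split_rhat(chains_out)
          else rep(NA_real_, npar)
  rhat_tb <- tibble(parameter = nm, rhat = as.numeric(rhat))
  if (any(is.finite(rhat) & rhat > 1.05))
    warn(sprintf("split-R-hat > 1.05 for: %s",
                 paste(nm[which(is.finite(rhat) & rhat > 1.05)],
                       collapse = ", ")))

  structure(list(
    draws = chains_out, posterior_mean = pm, rhat = rhat_tb,
    basis = basis, batch_levels = levels, p = p,
    y_center = y_c, y_scale = y_s, age_center = a_c, age_scale = a_s,
    likelihood = cfg$likelihood, config = cfg, n = length(y),
    bidx = bidx, gidx = gidx, sidx = sidx),
    class = "normative_fit")
}

#' @export
print.normative_fit <- function(x, ...) {
  cat(sprintf(
    "<normative_fit> %s likelihood, %d obs, %d batch level(s); max R-hat %.3f\n",
    x$likelihood, x$n, length(x$batch_levels),
    max(x$rhat$rhat, na.rm = TRUE)))
  invisible(x)
}

## Plug-in (posterior mean) parameters on the standardized scale.
plugin_params <- function(fit, draw = NULL) {
  th <- if (is.null(draw)) fit$posterior_mean else draw
  L <- length(fit$batch_levels)
  beta <- matrix(th[seq_len(L * fit$p)], fit$p, L)
  gamma <- matrix(th[L * fit$p + seq_len(2 * L)], 2, L)
  if (fit$likelihood == "shash") {
    eps <- th[fit$sidx[1]]
    delta <- if (is.null(draw))
      mean(exp(do.call(rbind, fit$draws)[, fit$sidx[2]]))
    else exp(th[fit$sidx[2]])
  } else { eps <- 0; delta <- 1 }
  mom <- shash_moments(eps, delta)
  list(beta = beta, gamma = gamma, eps = eps, delta = delta, mom = mom)
}

## Standardized-scale mu and sigma at given covariates.
mu_sigma_std <- function(fit, pp, age, batch) {
  X <- eval_basis(fit$basis, age)
  li <- match(as.character(batch), fit$batch_levels)
  if (anyNA(li)) abort("unknown batch level")
  a <- (age - fit$age_center) / fit$age_scale
  mu <- rowSums(X * t(pp$beta[, li, drop = FALSE]))
  sigma <- softplus(pp$gamma[1, li] + pp$gamma[2, li] * a) + 1e-6
  list(mu = mu, sigma = sigma)
}

#' Deviation z-scores ("latent index")
#'
#' Evaluates each observation's deviation from the fitted normative
#' distribution: the standardized residual is mapped through the inverse
#' sinh-arcsinh transform so that, if the model is correct, the scores are
#' standard normal. Under the Gaussian likelihood this reduces exactly to
#' `(y - mu) / sigma`. By default parameters are plugged in at their
#' posterior means; `method = "posterior"` averages the z-score over
#' posterior draws instead.
#'
#' @param fit A `normative_fit`.
#' @param y,age,batch Observations to score (ages must lie within the
#'   training spline support; there is no silent extrapolation).
#' @param method `"plugin"` (default) or `"posterior"`.
#' @param max_draws Posterior draws used when `method = "posterior"`.
#' @return Numeric vector of z-scores.
#' @export
latent_index <- function(fit, y, age, batch,
                         method = c("plugin", "posterior"),
                         max_draws = 200) {
  stopifnot(inherits(fit, "normative_fit"))
  method <- match.arg(method)
  ys <- (y - fit$y_center) / fit$y_scale
  score <- function(pp) {
    ms <- mu_sigma_std(fit, pp, age, batch)
    ystd <- (ys - ms$mu) / ms$sigma * sqrt(pp$mom$variance) + pp$mom$mean
    shash_forward(ystd, pp$eps, pp$delta)
  }
  if (method == "plugin") return(score(plugin_params(fit)))
  dr <- do.call(rbind, fit$draws)
  take <- round(seq(1, nrow(dr), length.out = min(max_draws, nrow(dr))))
  zs <- vapply(take, function(i) score(plugin_params(fit, dr[i, ])),
               numeric(length(y)))
  rowMeans(zs)
}

#' Normative percentile curves
#'
#' Posterior plug-in quantile curves of the fitted normative distribution
#' over an age grid, per batch. The curves are exactly coherent with
#' [latent_index()]: a point lying on the q-th curve scores
#' `qnorm(q)`.
#'
#' @param fit A `normative_fit`.
#' @param age_grid Ages at which to evaluate (within spline support).
#' @param batch Batch level(s); default all fitted levels.
#' @param quantiles Quantile levels in (0, 1).
#' @return Tibble with columns `age`, `batch`, `quantile`, `value`; for a
#'   fixed age and batch, `value` is strictly increasing in `quantile`.
#' @export
percentile_curves <- function(fit, age_grid,
                              batch = fit$batch_levels,
                              quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(fit, "normative_fit"))
  if (length(age_grid) == 0) abort("empty age grid")
  if (any(quantiles <= 0 | quantiles >= 1))
    abort("quantiles must lie strictly inside (0, 1)")
  pp <- plugin_params(fit)
  out <- list()
  for (b in batch) {
    ms <- mu_sigma_std(fit, pp, age_grid, rep(b, length(age_grid)))
    for (q in quantiles) {
      Sq <- shash_inverse(qnorm(q), pp$eps, pp$delta)
      val_std <- ms$mu + ms$sigma * (Sq - pp$mom$mean) /
        sqrt(pp$mom$variance)
      out[[length(out) + 1]] <- tibble(
        age = age_grid, batch = b, quantile = q,
        value = fit$y_center + fit$y_scale * val_std)
    }
  }
  bind_rows(out)
}

#' Normal quantile-quantile diagnostics for deviation scores
#'
#' Pairs the sorted z-scores with standard-normal plotting positions
#' `qnorm((i - 0.5) / n)` and reports the Kolmogorov-Smirnov distance to
#' the standard normal.
#'
#' @param z Numeric vector of deviation scores (n >= 20).
#' @return A tibble with `theoretical` and `empirical` columns; attributes
#'   `ks_stat`, `ks_p` and `normal` (logical flag at the 0.01 level).
#' @export
qq_diagnostics <- function(z) {
  if (length(z) < 20) abort("need at least 20 scores for QQ diagnostics")
  n <- length(z)
  tb <- tibble(theoretical = qnorm((seq_len(n) - 0.5) / n),
               empirical = sort(z))
  if (sd(z) < 1e-12) {
    ks <- max(abs(pnorm(z[1]) - c(0, 1)))
    attr(tb, "ks_stat") <- ks
    attr(tb, "ks_p") <- 0
    attr(tb, "normal") <- FALSE
    return(tb)
  }
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  attr(tb, "ks_stat") <- unname(kt$statistic)
  attr(tb, "ks_p") <- kt$p.value
  attr(tb, "normal") <- kt$p.value >= 0.01
  tb
}

#' @method tidy normative_fit
#' @export
tidy.normative_fit <- function(x, ...) {
  dr <- do.call(rbind, x$draws)
  tibble(parameter = colnames(dr),
         estimate = colMeans(dr),
         std.error = apply(dr, 2, sd),
         conf.low = apply(dr, 2, quantile, 0.025),
         conf.high = apply(dr, 2, quantile, 0.975)) |>
    left_join(x$rhat, by = "parameter")
}

#' @method glance normative_fit
#' @export
glance.normative_fit <- function(x, ...) {
  tibble(n = x$n, likelihood = x$likelihood,
         chains = x$config$chains, draws = x$config$draws,
         max_rhat = max(x$rhat$rhat, na.rm = TRUE),
         epsilon = plugin_params(x)$eps, delta = plugin_params(x)$delta)
}

#' @method autoplot normative_fit
#' @export
autoplot.normative_fit <- function(object, age_grid = NULL,
                                   quantiles = c(0.05, 0.25, 0.5, 0.75,
                                                 0.95), ...) {
  if (is.null(age_grid))
    age_grid <- seq(object$basis$bounds[1], object$basis$bounds[2],
                    length.out = 60)
  pc <- percentile_curves(object, age_grid, quantiles = quantiles)
  ggplot(pc, aes(x = .data$age, y = .data$value,
                 group = .data$quantile)) +
    geom_line(aes(alpha = 1 - abs(.data$quantile - 0.5))) +
    facet_wrap(~batch) +
    labs(x = "age (years)", y = "component value",
         title = "Normative percentile curves") +
    theme_minimal() + ggplot2::guides(alpha = "none")
}
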