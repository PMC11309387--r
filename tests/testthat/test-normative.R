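test_that("sinh-arcsinh transforms: identity, monotonicity, inversion", {
  y <- seq(-4, 4, length.out = 101)
  expect_equal(shash_forward(y, 0, 1), y, tolerance = 1e-14)
  expect_equal(shash_inverse(y, 0, 1), y, tolerance = 1e-14)

  f <- shash_forward(y, 0.5, 1.3)
  expect_true(all(diff(f) > 0))

  for (eps in c(-0.5, 0, 0.7)) for (del in c(0.6, 1, 1.4)) {
    z <- seq(-3, 3, length.out = 41)
    expect_lt(max(abs(shash_forward(shash_inverse(z, eps, del),
                                    eps, del) - z)), 1e-10)
    expect_lt(max(abs(shash_inverse(shash_forward(y, eps, del),
                                    eps, del) - y)), 1e-10)
  }
  expect_error(shash_forward(1, 0, -1), "> 0")
})

test_that("SHASH moments match numerical quadrature", {
  expect_equal(shash_moments(0, 1.2)$mean, 0, tolerance = 1e-12)
  expect_equal(shash_moments(0, 1)$variance, 1, tolerance = 1e-10)
  for (eps in c(0, 0.5)) for (del in c(0.8, 1, 1.3)) {
    mo <- shash_moments(eps, del)
    m_num <- integrate(function(z) shash_inverse(z, eps, del) * dnorm(z),
                       -Inf, Inf, rel.tol = 1e-12)$value
    v_num <- integrate(function(z)
      (shash_inverse(z, eps, del) - m_num)^2 * dnorm(z),
      -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(mo$mean, m_num, tolerance = 1e-6)
    expect_equal(mo$variance, v_num, tolerance = 1e-6)
  }
})

## One moderate Gaussian fit reused by several blocks below.
gauss_fit <- function() {
  cached("gauss_fit", {
    set.seed(77)
    n <- 300
    age <- runif(n, 20, 80)
    batch <- rep(c("F", "M"), length.out = n)
    y <- 3 + 0.5 * age + ifelse(batch == "M", 1, 0) + rnorm(n, sd = 4)
    fit <- fit_hbr(y, age, batch,
                   normative_config(likelihood = "gaussian", draws = 400,
                                    tune = 400, seed = 19))
    list(fit = fit, age = age, batch = batch, y = y)
  })
}

test_that("Gaussian fit recovers the linear age trend", {
  gf <- gauss_fit()
  pp <- latentmap:::plugin_params(gf$fit)
  grid <- seq(25, 75, length.out = 80)
  ms <- latentmap:::mu_sigma_std(gf$fit, pp, grid, rep("F", 80))
  mu <- gf$fit$y_center + gf$fit$y_scale * ms$mu
  slope <- coef(lm(mu ~ grid))[2]
  expect_lt(abs(slope - 0.5) / 0.5, 0.15)
  expect_true(all(gf$fit$rhat$rhat < 1.3, na.rm = TRUE))
})

test_that("Gaussian-limit z equals the closed form given the same mu/sigma", {
  gf <- gauss_fit()
  pp <- latentmap:::plugin_params(gf$fit)
  grid_age <- seq(21, 79, length.out = 1000)
  grid_y <- seq(-30, 80, length.out = 1000)
  ms <- latentmap:::mu_sigma_std(gf$fit, pp, grid_age, rep("F", 1000))
  z <- latent_index(gf$fit, grid_y, grid_age, rep("F", 1000))
  closed <- ((grid_y - gf$fit$y_center) / gf$fit$y_scale - ms$mu) /
    ms$sigma
  expect_lt(max(abs(z - closed)), 1e-8)
})

test_that("latent_index honours spline support and simple anchors", {
  gf <- gauss_fit()
  pp <- latentmap:::plugin_params(gf$fit)
  ages <- c(30, 50, 70)
  ms <- latentmap:::mu_sigma_std(gf$fit, pp, ages, rep("M", 3))
  y_mu <- gf$fit$y_center + gf$fit$y_scale * ms$mu
  expect_equal(latent_index(gf$fit, y_mu, ages, rep("M", 3)),
               rep(0, 3), tolerance = 1e-10)
  y_2s <- y_mu + 2 * gf$fit$y_scale * ms$sigma
  expect_equal(latent_index(gf$fit, y_2s, ages, rep("M", 3)),
               rep(2, 3), tolerance = 1e-10)
  expect_error(latent_index(gf$fit, 0, 101, "M"), "spline support")
})

test_that("percentile curves are coherent with the deviation scores", {
  gf <- gauss_fit()
  grid <- seq(25, 75, length.out = 9)
  pc <- percentile_curves(gf$fit, grid,
                          quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95))
  ## quantile monotonicity at every age and batch
  wide <- tidyr::pivot_wider(pc, names_from = "quantile",
                             values_from = "value")
  qcols <- as.matrix(wide[, c("0.05", "0.25", "0.5", "0.75", "0.95")])
  expect_true(all(diff(t(qcols)) > 0))

  ## symmetric case: the median curve is mu itself
  pp <- latentmap:::plugin_params(gf$fit)
  ms <- latentmap:::mu_sigma_std(gf$fit, pp, grid, rep("F", 9))
  med <- pc$value[pc$quantile == 0.5 & pc$batch == "F"]
  expect_equal(med, gf$fit$y_center + gf$fit$y_scale * ms$mu,
               tolerance = 1e-10)

  ## round trip: points on the 95% curve score qnorm(0.95)
  p95 <- dplyr::filter(pc, .data$quantile == 0.95)
  z <- latent_index(gf$fit, p95$value, p95$age, p95$batch)
  expect_lt(max(abs(z - qnorm(0.95))), 1e-6)

  expect_error(percentile_curves(gf$fit, numeric(0)), "empty")
  expect_error(percentile_curves(gf$fit, 50, quantiles = c(0, 0.5)),
               "inside")
})

test_that("fit input validation and degenerate cases error or warn", {
  expect_error(fit_hbr(c(1, NA, 3), c(1, 2, 3), c("a", "a", "a")),
               "non-finite")
  expect_error(fit_hbr(rnorm(30), rep(50, 30), rep("a", 30),
                       normative_config(draws = 10, tune = 10)),
               "unique age")
  expect_warning(
    fit_hbr(rnorm(60) + seq(0, 5, length.out = 60),
            seq(20, 80, length.out = 60),
            rep(c("a", "b"), each = 30),
            normative_config(likelihood = "gaussian", draws = 30,
                             tune = 30, n_knots = 1, seed = 2)),
    "fewer than 50")
})

test_that("gaussian and shash likelihoods agree when shape is identity-like", {
  set.seed(5)
  n <- 250
  age <- runif(n, 30, 70)
  batch <- rep(c("F", "M"), length.out = n)
  y <- 0.2 * age + ifelse(batch == "M", 0.5, 0) + rnorm(n)
  cfgs <- list(
    normative_config(likelihood = "gaussian", draws = 400, tune = 400,
                     seed = 4),
    normative_config(likelihood = "shash", draws = 400, tune = 400,
                     seed = 4))
  fits <- lapply(cfgs, function(cf) fit_hbr(y, age, batch, cf))
  z <- lapply(fits, latent_index, y = y, age = age, batch = batch)
  expect_lt(mean(abs(z[[1]] - z[[2]])), 0.05)
  ## shash shape posterior hovers near the identity on Gaussian data
  gl <- glance(fits[[2]])
  expect_lt(abs(gl$epsilon), 0.3)
  expect_lt(abs(log(gl$delta)), 0.3)
})

test_that("SHASH quantile curves agree with an independent ML fit (mgcv)", {
  skip_if_not_installed("mgcv")
  set.seed(12)
  n <- 500
  age <- runif(n, 20, 80)
  S <- shash_inverse(rnorm(n), 0.4, 1.2)
  y <- 1 + 0.08 * age + 1.5 * S
  fit <- fit_hbr(y, age, rep("all", n),
                 normative_config(draws = 500, tune = 500, seed = 3))
  grid <- seq(25, 75, length.out = 40)
  ours <- percentile_curves(fit, grid, quantiles = c(0.1, 0.5, 0.9))

  b <- mgcv::gam(list(y ~ s(age), ~1, ~1, ~1), family = mgcv::shash())
  pred <- predict(b, newdata = data.frame(age = grid))
  for (q in c(0.1, 0.5, 0.9)) {
    theirs <- b$family$qf(q, pred)
    mine <- ours$value[ours$quantile == q]
    expect_gt(cor(mine, theirs), 0.97)
    expect_lt(sqrt(mean((mine - theirs)^2)) / sd(y), 0.12)
  }
})

test_that("QQ diagnostics report the KS distance", {
  set.seed(3)
  z <- rnorm(1000)
  tb <- qq_diagnostics(z)
  expect_equal(nrow(tb), 1000)
  expect_lt(attr(tb, "ks_stat"), 0.05)
  expect_true(attr(tb, "normal"))

  cz <- qq_diagnostics(rep(1.3, 50))
  expect_false(attr(cz, "normal"))
  expect_gte(attr(cz, "ks_stat"), 0.4)

  expect_error(qq_diagnostics(rnorm(10)), "at least 20")
})

test_that("posterior summaries expose draws, intervals and diagnostics", {
  gf <- gauss_fit()
  td <- tidy(gf$fit)
  expect_true(all(c("estimate", "conf.low", "conf.high", "rhat") %in%
                    names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(gf$fit)
  expect_equal(gl$likelihood, "gaussian")
  expect_equal(gl$delta, 1)
})
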