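test_that("spherical correlation has the closed form and compact support", {
  expect_equal(spherical_correlation(0, 10), 1)
  expect_equal(spherical_correlation(10, 10), 0)
  expect_equal(spherical_correlation(5, 10), 0.3125)
  expect_equal(spherical_correlation(15, 10), 0)
  h <- seq(0, 30, by = 0.5)
  expect_true(all(diff(spherical_correlation(h, 12)) <= 1e-12))
  expect_error(spherical_correlation(-1, 10), class = "firexcess_invalid_argument")
  expect_error(spherical_correlation(1, 0), class = "firexcess_invalid_argument")
})

test_that("spherical covariance matrices are positive semidefinite on the plane", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:25, 1)
    D <- distance_matrix(runif(n, 0, 40), runif(n, 0, 40))
    H <- spherical_correlation(D, runif(1, 2, 60))
    expect_gte(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("Matheron estimator matches its definition", {
  # constant values -> zero semivariance in every bin
  g <- random_geometry(15, 3)
  sv0 <- empirical_semivariogram(rep(2, 15), g[, c("x_km", "y_km")])
  expect_true(all(sv0$bins$gamma == 0))
  # two points, values 0 and 2: gamma = (1/2) * 4 / 1 = 2
  sv2 <- empirical_semivariogram(c(0, 2), cbind(c(0, 1), c(0, 0)),
                                 n_bins = 1, max_dist_fraction = 1)
  expect_equal(sv2$bins$gamma, 2)
  expect_equal(sv2$bins$n_pairs, 1L)
  # hand-computed three-point fixture in one bin
  sv3 <- empirical_semivariogram(c(0, 1, 3), cbind(c(0, 1, 2), c(0, 0, 0)),
                                 n_bins = 1, max_dist_fraction = 1)
  # pairs: (0,1), (1,3), (0,3) -> squared diffs 1, 4, 9 -> mean/2 = 7/3
  expect_equal(sv3$bins$gamma, 7 / 3)
  expect_error(empirical_semivariogram(c(1, 2), cbind(c(0, 0), c(0, 0))),
               class = "firexcess_invalid_argument")
})

test_that("WLS fit inverts noise-free spherical semivariograms", {
  h <- seq(1, 19, by = 2)
  gm <- spherical_semivariance(h, nugget = 1, psill = 2, phi = 10)
  sv <- structure(list(bins = data.frame(mid = h, gamma = gm, n_pairs = 10),
                       max_dist = 20, cutoff = 20), class = "semivariogram")
  fit <- fit_spherical_wls(sv)
  expect_equal(fit$nugget, 1, tolerance = 1e-6)
  expect_equal(fit$psill, 2, tolerance = 1e-6)
  expect_equal(fit$range_km, 10, tolerance = 1e-6)

  # scale equivariance: doubling values quadruples nugget and sill
  sv4 <- sv
  sv4$bins$gamma <- 4 * sv$bins$gamma
  fit4 <- fit_spherical_wls(sv4)
  expect_equal(fit4$nugget, 4, tolerance = 1e-5)
  expect_equal(fit4$psill, 8, tolerance = 1e-5)
  expect_equal(fit4$range_km, fit$range_km, tolerance = 1e-4)

  expect_error(fit_spherical_wls(
    structure(list(bins = data.frame(mid = h, gamma = 0, n_pairs = 10),
                   max_dist = 20, cutoff = 20), class = "semivariogram")),
    class = "firexcess_invalid_argument")
})

test_that("semivariogram of GP fields tracks tau2 + sigma2 (1 - rho)", {
  g <- gen_geometry(80, seed = 10)
  reps <- 30
  acc <- NULL
  for (r in seq_len(reps)) {
    y <- gen_gp_field(g, 0, sigma2 = 2, tau2 = 1, phi = 25, seed = 500 + r)
    sv <- empirical_semivariogram(y, g[, c("x_km", "y_km")], n_bins = 8)
    acc <- if (is.null(acc)) sv$bins$gamma else acc + sv$bins$gamma
  }
  gbar <- acc / reps
  sv <- empirical_semivariogram(rep(0, 80), g[, c("x_km", "y_km")], n_bins = 8)
  expected <- spherical_semivariance(sv$bins$mid, 1, 2, 25)
  expect_lt(max(abs(gbar - expected) / expected), 0.25)
})

test_that("MCMC is seed-deterministic and passes stationarity sanity checks", {
  g <- gen_geometry(40, seed = 2)
  y <- gen_gp_field(g, 3, sigma2 = 2, tau2 = 1, phi = 20, seed = 8)
  cfg <- bhm_config(n_samples = 1500, burn_in = 500, seed = 4)
  p1 <- run_mcmc(y, g[, c("x_km", "y_km")], cfg)
  p2 <- run_mcmc(y, g[, c("x_km", "y_km")], cfg)
  expect_identical(p1$beta0, p2$beta0)
  expect_identical(p1$W, p2$W)
  expect_equal(length(p1$beta0), 1000)
  expect_true(all(p1$sigma2 > 0) && all(p1$tau2 > 0))
  expect_true(all(p1$phi >= p1$phi_support[1] & p1$phi <= p1$phi_support[2]))
  expect_gt(p1$accept_rate_phi, 0.05)
  # split-half mean difference < 3 SE, with batch-means SEs to account for
  # chain autocorrelation
  bm_se <- function(ch, n_batch = 10) {
    bm <- colMeans(matrix(ch, ncol = n_batch))
    sd(bm) / sqrt(n_batch)
  }
  for (ch in list(p1$sigma2, p1$tau2, p1$phi)) {
    a <- ch[1:500]; b <- ch[501:1000]
    se <- sqrt(bm_se(a)^2 + bm_se(b)^2)
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
  expect_error(run_mcmc(c(y[-1], NA), g[, c("x_km", "y_km")], cfg),
               class = "firexcess_invalid_argument")
})

test_that("with the spatial effect fixed at zero the intercept posterior is conjugate", {
  set.seed(31)
  y <- rnorm(60, mean = 4, sd = 1.5)
  coords <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  tau2 <- 1.5^2
  cfg <- bhm_config(n_samples = 6000, burn_in = 1000, fix_w_zero = TRUE,
                    fix_tau2 = tau2, seed = 6)
  post <- run_mcmc(y, coords, cfg)
  v <- 1 / (60 / tau2 + 1 / cfg$beta_var)
  m <- v * sum(y) / tau2
  expect_equal(mean(post$beta0), m, tolerance = 0.01)
  expect_equal(sd(post$beta0), sqrt(v), tolerance = 0.05)
  expect_true(all(post$W == 0))
})

test_that("near-constant response yields a matching degenerate fit", {
  g <- random_geometry(20, 9)
  y <- rep(2.5, 20) + rnorm(20, 0, 1e-4)
  cfg <- bhm_config(n_samples = 1200, burn_in = 200,
                    sigma2_scale = 1e-6, tau2_scale = 1e-6, seed = 3)
  post <- run_mcmc(y, g[, c("x_km", "y_km")], cfg)
  expect_equal(unname(colMeans(post$fitted)), rep(2.5, 20), tolerance = 1e-3)
})

test_that("posterior smoothing shrinks unit-level variance", {
  g <- gen_geometry(60, seed = 12)
  y <- gen_gp_field(g, 1, sigma2 = 1.5, tau2 = 1, phi = 25, seed = 13)
  post <- run_mcmc(y, g[, c("x_km", "y_km")],
                   bhm_config(n_samples = 2000, burn_in = 500, seed = 14))
  # no-pooling estimate of a unit is its own observation with sd ~ sd(y)
  expect_lt(mean(post$summary$sd), sd(y))
})

test_that("SNR is posterior mean over posterior sd", {
  draws <- c(2, 2, 2, 4)
  fake <- structure(list(
    beta0 = rep(0, 100), summary = data.frame(
      unit_id = c("a", "b"), mean = c(mean(draws), 0), sd = c(sd(draws), 1),
      w_mean = c(0, 0), w_sd = c(1, 1))), class = "bhm_posterior")
  expect_equal(unname(snr_map(fake)), c(2.5, 0))
  expect_equal(unname(snr_map(fake, numerator = "w")), c(0, 0))
})

test_that("prior sensitivity: doubled/halved IG scales barely move the fit", {
  g <- gen_geometry(50, seed = 20)
  y <- gen_gp_field(g, 2, sigma2 = 2, tau2 = 1, phi = 20, seed = 21)
  fits <- lapply(c(0.5, 1, 2), function(f) {
    sv <- fit_spherical_wls(empirical_semivariogram(y, g[, c("x_km", "y_km")]))
    cfg <- bhm_config(n_samples = 1500, burn_in = 500, seed = 7,
                      sigma2_scale = f * max(sv$psill, 1e-3),
                      tau2_scale = f * max(sv$nugget, 1e-3))
    colMeans(run_mcmc(y, g[, c("x_km", "y_km")], cfg)$fitted)
  })
  ref <- fits[[2]]
  scale <- diff(range(ref))
  expect_lt(max(abs(fits[[1]] - ref)) / scale, 0.10)
  expect_lt(max(abs(fits[[3]] - ref)) / scale, 0.10)
})
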