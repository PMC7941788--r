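#' Configuration for the Bayesian hierarchical spatial model
#'
#' Sampler sizes default to 10,000 draws with 7,500 burn-in. Priors:
#' `beta ~ N(0, beta_var)` (vague), `sigma2` and `tau2 ~ Inverse-Gamma(2,
#' scale)` with scales taken from the semivariogram WLS fit (partial sill
#' and nugget respectively, giving prior mean equal to the empirical
#' estimate), and `phi ~ Uniform(d_min, d_max)` over the observed nonzero
#' pairwise-distance span. `phi` is updated by random-walk Metropolis on a
#' logit transform of its support.
#'
#' @param n_samples total MCMC draws (default 10000).
#' @param burn_in discarded initial draws (default 7500; must be < n_samples).
#' @param beta_var prior variance of the intercept (default 1e6).
#' @param ig_shape inverse-gamma shape for both variances (default 2).
#' @param sigma2_scale,tau2_scale inverse-gamma scales; `NULL` (default)
#'   sets them from the semivariogram fit at run time.
#' @param phi_proposal_sd random-walk sd on the transformed range.
#' @param fix_w_zero hold the spatial effect at exactly zero (skips W,
#'   sigma2 and phi updates) — reduces the model to an i.i.d. normal mean
#'   model, useful as a conjugate closed-form oracle.
#' @param fix_tau2 optional fixed value for tau2 (skips its update).
#' @param jitter diagonal jitter used if the spherical correlation matrix is
#'   numerically singular.
#' @param seed integer seed.
#' @return object of class `bhm_config`.
#' @export
bhm_config <- function(n_samples = 10000, burn_in = 7500, beta_var = 1e6,
                       ig_shape = 2, sigma2_scale = NULL, tau2_scale = NULL,
                       phi_proposal_sd = 0.6, fix_w_zero = FALSE,
                       fix_tau2 = NULL, jitter = 1e-8, seed = 1) {
  if (burn_in >= n_samples) stop_invalid("burn_in must be < n_samples")
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), beta_var = beta_var,
                 ig_shape = ig_shape, sigma2_scale = sigma2_scale,
                 tau2_scale = tau2_scale, phi_proposal_sd = phi_proposal_sd,
                 fix_w_zero = isTRUE(fix_w_zero), fix_tau2 = fix_tau2,
                 jitter = jitter, seed = as.integer(seed)),
            class = "bhm_config")
}

#' Fit the two-stage spatial Bayesian hierarchical model by MCMC
#'
#' Stage 1 (data model): `y_i = beta0 + W_i + eps_i`, `eps ~ N(0, tau2 I)` —
#' the `y_i` are conditionally independent given `W`. Stage 2 (process
#' model): `W ~ N(0, sigma2 H(phi))` with `H` the spherical, isotropic
#' correlation over planar km coordinates. X is intercept-only; the response
#' is typically the per-unit excess count aggregated over the exposed days.
#'
#' Sampling is Metropolis-within-Gibbs: conjugate normal updates for `beta0`
#' and `W`, conjugate inverse-gamma updates for `tau2` and `sigma2`, and
#' random-walk Metropolis on a logit transform of `phi` over its uniform
#' support, with the acceptance rate reported. Inverse-gamma prior scales
#' and the `phi` start default to the empirical-semivariogram WLS fit.
#'
#' @param y per-unit response (aggregated excess counts), length n.
#' @param coords matrix/data.frame of planar (x, y) km coordinates.
#' @param config a [bhm_config()].
#' @param ids optional unit ids for labelling output (default rownames or
#'   `U1..Un`).
#' @return object of class `bhm_posterior`: retained draws (`beta0`,
#'   `sigma2`, `tau2`, `phi` vectors; `W` and `fitted` matrices draws x n),
#'   per-unit `summary` data.frame (unit_id, mean, sd), `accept_rate_phi`,
#'   `phi_support`, and the `config`.
#' @export
run_mcmc <- function(y, coords, config = bhm_config(), ids = NULL) {
  stopifnot(inherits(config, "bhm_config"))
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop_invalid("y must be finite")
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- length(y)
  if (nrow(coords) != n) stop_invalid("coords must have one row per y value")
  if (is.null(ids)) ids <- rownames(coords) %||% paste0("U", seq_len(n))

  D <- distance_matrix(coords[, 1], coords[, 2])
  dpos <- D[upper.tri(D)]
  dpos <- dpos[dpos > 0]
  d_min <- min(dpos); d_max <- max(dpos)

  # semivariogram-derived prior scales and phi start
  s2_scale <- config$sigma2_scale
  t2_scale <- config$tau2_scale
  phi <- (d_min + d_max) / 2
  if ((is.null(s2_scale) || is.null(t2_scale)) && !config$fix_w_zero) {
    fit <- tryCatch(
      fit_spherical_wls(empirical_semivariogram(y, coords)),
      error = function(e) list(nugget = stats::var(y) / 2,
                               psill = stats::var(y) / 2,
                               range_km = (d_min + d_max) / 2))
    if (is.null(s2_scale)) s2_scale <- max(fit$psill, 1e-3)
    if (is.null(t2_scale)) t2_scale <- max(fit$nugget, 1e-3)
    phi <- min(max(fit$range_km, d_min * 1.01), d_max * 0.99)
  }
  if (is.null(s2_scale)) s2_scale <- max(stats::var(y) / 2, 1e-3)
  if (is.null(t2_scale)) t2_scale <- max(stats::var(y) / 2, 1e-3)
  a_ig <- config$ig_shape

  set.seed(config$seed)
  beta <- mean(y)
  W <- rep(0, n)
  sigma2 <- s2_scale
  tau2 <- config$fix_tau2 %||% t2_scale

  chol_H <- function(phi) {
    H <- spherical_correlation(D, phi)
    tryCatch(chol(H), error = function(e) {
      warning("H(phi) numerically singular; adding diagonal jitter")
      chol(H + diag(config$jitter, n))
    })
  }
  cholH <- if (!config$fix_w_zero) chol_H(phi) else NULL
  # log N(W; 0, sigma2 H) up to constants, via the cached Cholesky of H
  logdens_W <- function(cholH, W, sigma2) {
    v <- backsolve(cholH, W, transpose = TRUE)
    -sum(log(diag(cholH))) - 0.5 * n * log(sigma2) - 0.5 * sum(v^2) / sigma2
  }
  to_phi <- function(eta) d_min + (d_max - d_min) * stats::plogis(eta)
  to_eta <- function(phi) stats::qlogis((phi - d_min) / (d_max - d_min))
  log_jac <- function(eta) {
    p <- stats::plogis(eta)
    log(d_max - d_min) + log(p) + log1p(-p)
  }
  eta <- to_eta(phi)

  keep <- config$n_samples - config$burn_in
  out_beta <- numeric(keep); out_s2 <- numeric(keep)
  out_t2 <- numeric(keep); out_phi <- numeric(keep)
  out_W <- matrix(0, keep, n)
  acc <- 0L; n_prop <- 0L

  for (it in seq_len(config$n_samples)) {
    # beta | . : conjugate normal
    v_beta <- 1 / (n / tau2 + 1 / config$beta_var)
    m_beta <- v_beta * sum(y - W) / tau2
    beta <- stats::rnorm(1, m_beta, sqrt(v_beta))

    if (!config$fix_w_zero) {
      # W | . : N(Q^-1 (y - beta)/tau2, Q^-1), Q = Hinv/sigma2 + I/tau2
      Hinv <- chol2inv(cholH)
      Q <- Hinv / sigma2 + diag(1 / tau2, n)
      cQ <- chol(Q)
      mu_W <- backsolve(cQ, backsolve(cQ, (y - beta) / tau2, transpose = TRUE))
      W <- mu_W + backsolve(cQ, stats::rnorm(n))

      # sigma2 | . : IG(a + n/2, scale + W' Hinv W / 2)
      qf <- sum(backsolve(cholH, W, transpose = TRUE)^2)
      sigma2 <- 1 / stats::rgamma(1, a_ig + n / 2, rate = s2_scale + qf / 2)

      # phi | . : random-walk Metropolis on logit scale, uniform prior
      eta_prop <- eta + stats::rnorm(1, 0, config$phi_proposal_sd)
      cholH_prop <- chol_H(to_phi(eta_prop))
      log_r <- logdens_W(cholH_prop, W, sigma2) + log_jac(eta_prop) -
               logdens_W(cholH, W, sigma2) - log_jac(eta)
      n_prop <- n_prop + 1L
      if (log(stats::runif(1)) < log_r) {
        eta <- eta_prop; phi <- to_phi(eta); cholH <- cholH_prop
        acc <- acc + 1L
      }
    }

    # tau2 | . : IG(a + n/2, scale + RSS/2)
    if (is.null(config$fix_tau2)) {
      rss <- sum((y - beta - W)^2)
      tau2 <- 1 / stats::rgamma(1, a_ig + n / 2, rate = t2_scale + rss / 2)
    }

    if (it > config$burn_in) {
      j <- it - config$burn_in
      out_beta[j] <- beta; out_s2[j] <- sigma2
      out_t2[j] <- tau2; out_phi[j] <- phi
      out_W[j, ] <- W
    }
  }

  fitted <- out_beta + out_W
  summ <- data.frame(unit_id = ids,
                     mean = colMeans(fitted),
                     sd = apply(fitted, 2, stats::sd),
                     w_mean = colMeans(out_W),
                     w_sd = apply(out_W, 2, stats::sd),
                     stringsAsFactors = FALSE)
  structure(list(beta0 = out_beta, sigma2 = out_s2, tau2 = out_t2,
                 phi = out_phi, W = out_W, fitted = fitted,
                 summary = summ,
                 accept_rate_phi = if (n_prop) acc / n_prop else NA_real_,
                 phi_support = c(d_min, d_max), config = config),
            class = "bhm_posterior")
}

#' Per-unit signal-to-noise ratio of the smoothed excess
#'
#' `SNR_i = posterior mean / posterior SD` of the fitted excess
#' `beta0 + W_i` (default) or of the spatial effect `W_i` alone. The sign of
#' the SNR equals the sign of the posterior mean; |SNR| around 2 is the
#' conventional precision benchmark.
#'
#' @param posterior a [run_mcmc()] result with >= 100 retained draws.
#' @param numerator `"fitted"` (default, `beta0 + W_i`) or `"w"`.
#' @return named numeric vector of per-unit SNR values.
#' @export
snr_map <- function(posterior, numerator = c("fitted", "w")) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(posterior, "bhm_posterior"))
  if (length(posterior$beta0) < 100)
    stop_invalid("need >= 100 retained draws for a stable SNR")
  s <- posterior$summary
  snr <- if (numerator == "fitted") s$mean / s$sd else s$w_mean / s$w_sd
  if (any(!is.finite(snr)))
    stop(errorCondition("zero posterior SD encountered",
                        class = c("firexcess_internal_error", "error")))
  names(snr) <- s$unit_id
  snr
}

#' @export
print.bhm_posterior <- function(x, ...) {
  cat("BHM posterior:", length(x$beta0), "retained draws over",
      ncol(x$W), "units\n")
  cat(sprintf("  beta0 %.3f  sigma2 %.3f  tau2 %.3f  phi %.1f km (accept %.2f)\n",
              mean(x$beta0), mean(x$sigma2), mean(x$tau2), mean(x$phi),
              x$accept_rate_phi))
  invisible(x)
}
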