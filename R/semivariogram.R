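#' Spherical correlation function
#'
#' `rho(h) = 1 - 1.5 (h/phi) + 0.5 (h/phi)^3` for `0 <= h <= phi` and
#' exactly 0 beyond the range `phi`. Compactly supported and a valid
#' (positive semidefinite) correlation model in up to three dimensions.
#'
#' @param h nonnegative distance(s), km.
#' @param phi range parameter, km (> 0).
#' @return correlation value(s) in `[0, 1]`.
#' @examples
#' spherical_correlation(c(0, 5, 10, 20), phi = 10)
#' @export
spherical_correlation <- function(h, phi) {
  assert_scalar_number(phi, "phi", positive = TRUE)
  if (any(!is.finite(h)) || any(h < 0)) stop_invalid("h must be nonnegative and finite")
  r <- h / phi
  out <- 1 - 1.5 * r + 0.5 * r^3
  out[h > phi] <- 0
  out
}

# theoretical semivariogram of the spherical model
spherical_semivariance <- function(h, nugget, psill, phi) {
  nugget + psill * (1 - spherical_correlation(h, phi))
}

#' Empirical (Matheron) semivariogram
#'
#' `gamma_hat(h) = (1 / (2 N(h))) * sum_{pairs in bin} (z_i - z_j)^2` over
#' equal-width distance bins up to `max_dist_fraction` of the maximum
#' pairwise distance. Bins with no pairs are dropped.
#'
#' @param values per-unit numeric values.
#' @param coords matrix/data.frame of planar (x, y) km coordinates.
#' @param n_bins number of distance bins (default 15).
#' @param max_dist_fraction fraction of the maximum pairwise distance to bin
#'   up to (default 0.5, the usual variography cutoff).
#' @return object of class `semivariogram`: data.frame `bins` (mid, gamma,
#'   n_pairs) plus `max_dist`.
#' @export
empirical_semivariogram <- function(values, coords, n_bins = 15,
                                    max_dist_fraction = 0.5) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- length(values)
  if (n < 2 || nrow(coords) != n) stop_invalid("values and coords must match, n >= 2")
  D <- as.numeric(stats::dist(coords))
  if (max(D) == 0) stop_invalid("all points coincident; semivariogram undefined")
  dz2 <- as.numeric(stats::dist(values))^2
  cutoff <- max_dist_fraction * max(D)
  keep <- D <= cutoff & D > 0
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(D[keep], breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(dz2[keep], bin, function(v) mean(v) / 2)
  npairs <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  present <- sort(unique(bin))
  bins <- data.frame(mid = mids[present],
                     gamma = as.numeric(gamma[as.character(present)]),
                     n_pairs = npairs[present])
  structure(list(bins = bins, max_dist = max(D), cutoff = cutoff),
            class = "semivariogram")
}

#' Weighted least-squares fit of the spherical semivariogram
#'
#' Minimizes `sum_bins N(h) * (gamma_hat(h) - gamma_model(h))^2` over
#' nonnegative nugget and partial sill and positive range. The fit profiles
#' out (nugget, partial sill), which enter the model linearly, by weighted
#' (nonnegativity-clamped) least squares inside a 1-D golden-section search
#' over the range — robust and accurate to optimizer tolerance. Used to set
#' the inverse-gamma prior scales and the range starting value for the MCMC.
#'
#' @param sv a [empirical_semivariogram()] object.
#' @return list with `nugget`, `psill`, `range_km`, `wsse`.
#' @export
fit_spherical_wls <- function(sv) {
  stopifnot(inherits(sv, "semivariogram"))
  b <- sv$bins
  if (nrow(b) < 4) stop_invalid("need at least 4 nonempty semivariogram bins")
  if (all(b$gamma <= .Machine$double.eps))
    stop_invalid("semivariogram is flat at zero: data look like pure noise or constants")
  h <- b$mid; g <- b$gamma; w <- b$n_pairs

  # for fixed range phi, gamma_model = nugget + psill * f(h); weighted LS in
  # (nugget, psill) with nonnegativity by case analysis
  profile_fit <- function(phi) {
    f <- 1 - spherical_correlation(h, phi)
    X <- cbind(1, f)
    XtWX <- crossprod(X, w * X)
    XtWg <- crossprod(X, w * g)
    beta <- tryCatch(solve(XtWX, XtWg), error = function(e) c(0, 0))
    cand <- list(as.numeric(beta))
    # clamped alternatives
    cand <- c(cand,
              list(c(0, sum(w * f * g) / sum(w * f^2))),        # nugget = 0
              list(c(sum(w * g) / sum(w), 0)))                  # psill = 0
    best <- NULL; best_sse <- Inf
    for (p in cand) {
      p <- pmax(p, 0)
      sse <- sum(w * (g - (p[1] + p[2] * f))^2)
      if (sse < best_sse) { best_sse <- sse; best <- p }
    }
    list(par = best, sse = best_sse)
  }

  phis <- seq(min(h) / 2, sv$max_dist * 1.5, length.out = 60)
  sses <- vapply(phis, function(p) profile_fit(p)$sse, numeric(1))
  phi0 <- phis[which.min(sses)]
  lo <- max(min(h) / 4, phi0 - diff(range(phis)) / 59)
  hi <- min(sv$max_dist * 2, phi0 + diff(range(phis)) / 59)
  op <- stats::optimize(function(p) profile_fit(p)$sse, c(lo, hi), tol = 1e-10)
  phi_hat <- op$minimum
  pf <- profile_fit(phi_hat)
  list(nugget = pf$par[1], psill = pf$par[2], range_km = phi_hat,
       wsse = pf$sse)
}
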