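#' Generate synthetic spatial-unit geometry
#'
#' Draws `n_units` population-weighted centroids uniformly inside a planar
#' bounding box, standing in for ZIP-code centroids in projected km
#' coordinates. Populations are lognormal draws rounded up and are used only
#' as optional sampling weights downstream; there is no population-offset
#' modelling.
#'
#' @param n_units number of spatial units (>= 4).
#' @param bbox_km numeric length-4 `c(xmin, ymin, xmax, ymax)` in km.
#' @param seed integer seed; output is deterministic given the seed.
#' @param pop_meanlog,pop_sdlog lognormal parameters of the population draw.
#' @return data.frame with columns `unit_id`, `x_km`, `y_km`, `population`.
#' @examples
#' g <- gen_geometry(10, seed = 1)
#' range(g$x_km)
#' @export
gen_geometry <- function(n_units, bbox_km = c(0, 0, 60, 80), seed = 1,
                         pop_meanlog = log(2e4), pop_sdlog = 0.7) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 4)
    stop_invalid("n_units must be a single integer >= 4")
  if (length(bbox_km) != 4L || !all(is.finite(bbox_km)) ||
      bbox_km[3] <= bbox_km[1] || bbox_km[4] <= bbox_km[2])
    stop_invalid("bbox_km must be c(xmin, ymin, xmax, ymax) with positive area")
  n_units <- as.integer(n_units)
  set.seed(as.integer(seed))
  out <- data.frame(
    unit_id = sprintf("Z%03d", seq_len(n_units)),
    x_km = stats::runif(n_units, bbox_km[1], bbox_km[3]),
    y_km = stats::runif(n_units, bbox_km[2], bbox_km[4]),
    population = as.integer(ceiling(stats::rlnorm(n_units, pop_meanlog, pop_sdlog))),
    stringsAsFactors = FALSE
  )
  attr(out, "bbox_km") <- as.numeric(bbox_km)
  out
}

#' Relative smoke-plume excess at unit locations
#'
#' Anisotropic Gaussian plume kernel aligned with the wind: for a unit at
#' downwind distance `s` (projection of the fire-to-unit vector on the wind
#' unit vector) and crosswind offset `t`, the relative excess is
#' `A * exp(-s^2 / (2 L^2) - t^2 / (2 W^2))` for `s >= 0` and, by default,
#' exactly 0 strictly upwind (`s < 0`), emulating the sharp
#' downwind/upwind contrast of wind-driven smoke transport.
#'
#' @param unit_xy matrix or data.frame of unit coordinates (km), columns x, y.
#' @param fire_xy numeric length-2 fire location (km).
#' @param wind_vector numeric length-2 nonzero wind (transport direction, km).
#' @param A peak relative excess at the fire location (dimensionless, > 0).
#' @param L,W downwind and crosswind kernel scales in km (> 0).
#' @param sharp_cutoff zero out strictly-upwind units (default `TRUE`);
#'   `FALSE` uses the smooth two-sided kernel.
#' @return numeric vector of relative excesses in `[0, A]`.
#' @export
plume_exposure <- function(unit_xy, fire_xy, wind_vector, A, L, W,
                           sharp_cutoff = TRUE) {
  assert_scalar_number(A, "A", positive = TRUE)
  assert_scalar_number(L, "L", positive = TRUE)
  assert_scalar_number(W, "W", positive = TRUE)
  if (length(wind_vector) != 2L || !all(is.finite(wind_vector)) ||
      sum(wind_vector^2) == 0)
    stop_invalid("wind_vector must be a nonzero length-2 vector")
  if (length(fire_xy) != 2L || !all(is.finite(fire_xy)))
    stop_invalid("fire_xy must be a finite length-2 vector")
  xy <- as.matrix(unit_xy)[, 1:2, drop = FALSE]
  u <- wind_vector / sqrt(sum(wind_vector^2))
  d <- sweep(xy, 2, as.numeric(fire_xy))
  s <- d %*% u                      # downwind distance
  t <- d %*% c(-u[2], u[1])         # crosswind offset
  e <- A * exp(-s^2 / (2 * L^2) - t^2 / (2 * W^2))
  if (sharp_cutoff) e[s < 0] <- 0
  as.numeric(e)
}

#' Synthetic scenario configuration
#'
#' Bundles the parameters of the count-panel generator. Defaults emulate the
#' San Diego setting: 108 units in a 60 x 80 km box, a fall study window,
#' per-unit Poisson baselines whose county-wide daily mean per unit sits in
#' the observed 0.3--0.5 band, mild weekday structure, and a mid-county fire
#' whose broad smoke swath blankets the downwind (coastal, western) half of
#' the domain on every exposed day under a steady offshore wind. A wind
#' reversal (offshore to onshore, migrating the excess inland) can be
#' injected by supplying per-day `wind_vectors` with a flipped sign for the
#' later days.
#'
#' @param date_start,date_end first and last calendar date of the panel.
#' @param baseline_log_mean,baseline_log_sd lognormal parameters of the
#'   per-unit Poisson rate `lambda_i` (defaults give mean rate ~ 0.40/day).
#' @param dow_effects 7 positive multipliers, Monday..Sunday, mean 1.
#' @param fire_location,plume_amplitude,plume_length,plume_width plume
#'   kernel parameters (km; amplitude dimensionless, >= 0).
#' @param exposed_dates dates of smoke exposure (within the span).
#' @param wind_vectors list of length-2 wind vectors, one per exposed date
#'   (recycled if a single vector is given). Default is a steady offshore
#'   west-southwest transport on every exposed day.
#' @param population_weighted scale `lambda_i` by relative population.
#' @param sharp_cutoff see [plume_exposure()].
#' @param seed integer seed for the panel draw.
#' @return an object of class `scenario_config` (a list).
#' @export
scenario_config <- function(date_start = "2007-09-01",
                            date_end = "2007-11-30",
                            baseline_log_mean = log(0.48) - 0.5 * 0.45^2,
                            baseline_log_sd = 0.45,
                            dow_effects = c(1.05, 1.05, 1.05, 1.05, 1.05, 0.90, 0.85),
                            fire_location = c(30, 40),
                            plume_amplitude = 1.0,
                            plume_length = 150,
                            plume_width = 100,
                            exposed_dates = seq(as.Date("2007-10-22"),
                                                as.Date("2007-10-26"), by = "day"),
                            wind_vectors = NULL,
                            population_weighted = FALSE,
                            sharp_cutoff = TRUE,
                            seed = 1) {
  date_start <- as_date_strict(date_start, "date_start")
  date_end <- as_date_strict(date_end, "date_end")
  if (date_end < date_start) stop_invalid("date_end before date_start")
  exposed_dates <- as_date_strict(exposed_dates, "exposed_dates")
  if (any(exposed_dates < date_start | exposed_dates > date_end))
    stop_invalid("exposed_dates must lie within [date_start, date_end]")
  if (length(dow_effects) != 7L || any(!is.finite(dow_effects)) ||
      any(dow_effects <= 0))
    stop_invalid("dow_effects must be 7 positive multipliers")
  assert_scalar_number(plume_amplitude, "plume_amplitude", nonneg = TRUE)
  if (is.null(wind_vectors)) {
    # steady offshore transport toward the coast
    wind_vectors <- rep(list(c(-1, -0.15)), length(exposed_dates))
  }
  if (is.numeric(wind_vectors) && length(wind_vectors) == 2L)
    wind_vectors <- list(wind_vectors)
  wind_vectors <- rep(wind_vectors, length.out = length(exposed_dates))
  structure(list(
    date_start = date_start, date_end = date_end,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dow_effects = as.numeric(dow_effects),
    fire_location = as.numeric(fire_location),
    plume_amplitude = plume_amplitude,
    plume_length = plume_length, plume_width = plume_width,
    exposed_dates = exposed_dates, wind_vectors = wind_vectors,
    population_weighted = isTRUE(population_weighted),
    sharp_cutoff = isTRUE(sharp_cutoff),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Simulate a daily count panel with known ground truth
#'
#' Counts are `Y[i, d] ~ Poisson(lambda_i * dow(d) * (1 + e_i(d)))` where
#' `lambda_i` is a per-unit lognormal baseline rate, `dow(d)` a weekday
#' multiplier, and `e_i(d)` the relative plume excess on exposed days (0
#' otherwise). The returned ground truth records the true expected excess
#' `lambda_i * dow(d) * e_i(d)` for every (unit, exposed date).
#'
#' @param geometry data.frame from [gen_geometry()] (or with the same columns).
#' @param scenario a [scenario_config()].
#' @param lambda optional per-unit baseline rates overriding the lognormal
#'   draw (length `nrow(geometry)`).
#' @return list with `panel` (unit_id, date, count), `truth`
#'   (unit_id, date, true_excess; exposed dates only), and `lambda`.
#' @export
gen_count_panel <- function(geometry, scenario = scenario_config(),
                            lambda = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (anyDuplicated(geometry$unit_id)) stop_invalid("geometry unit_ids must be unique")
  n <- nrow(geometry)
  dates <- seq(scenario$date_start, scenario$date_end, by = "day")
  set.seed(scenario$seed)
  if (is.null(lambda)) {
    lambda <- stats::rlnorm(n, scenario$baseline_log_mean, scenario$baseline_log_sd)
    if (scenario$population_weighted)
      lambda <- lambda * geometry$population / mean(geometry$population)
  } else {
    if (length(lambda) != n || any(lambda < 0))
      stop_invalid("lambda must be nonnegative, one value per unit")
  }

  # relative excess per unit x exposed day
  e_mat <- matrix(0, n, length(scenario$exposed_dates))
  if (scenario$plume_amplitude > 0) {
    for (j in seq_along(scenario$exposed_dates)) {
      e_mat[, j] <- plume_exposure(
        geometry[, c("x_km", "y_km")], scenario$fire_location,
        scenario$wind_vectors[[j]], scenario$plume_amplitude,
        scenario$plume_length, scenario$plume_width,
        sharp_cutoff = scenario$sharp_cutoff)
    }
  }

  dowv <- scenario$dow_effects[weekday_index(dates)]
  exp_idx <- match(dates, scenario$exposed_dates)  # NA when not exposed
  mu <- outer(lambda, dowv)                         # n x n_dates baseline mean
  rel <- matrix(0, n, length(dates))
  on <- which(!is.na(exp_idx))
  if (length(on)) rel[, on] <- e_mat[, exp_idx[on], drop = FALSE]
  counts <- matrix(stats::rpois(n * length(dates), mu * (1 + rel)), n)

  panel <- data.frame(
    unit_id = rep(geometry$unit_id, times = length(dates)),
    date = rep(dates, each = n),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  mu_exp <- outer(lambda, scenario$dow_effects[weekday_index(scenario$exposed_dates)])
  truth <- data.frame(
    unit_id = rep(geometry$unit_id, times = length(scenario$exposed_dates)),
    date = rep(scenario$exposed_dates, each = n),
    true_excess = as.numeric(mu_exp * e_mat),
    stringsAsFactors = FALSE
  )
  list(panel = panel, truth = truth, lambda = lambda)
}

#' Draw one realization of the spatial Gaussian-process model
#'
#' Simulates `Y = beta0 + W + eps` with `W ~ N(0, sigma2 * H(phi))` for the
#' spherical correlation `H` and `eps ~ N(0, tau2 * I)` — exactly the
#' process stage of the Bayesian hierarchical model, with known parameters,
#' for validation and parameter-recovery studies.
#'
#' @param geometry data.frame with `x_km`, `y_km`.
#' @param beta0 intercept.
#' @param sigma2 partial sill (spatial variance, > 0).
#' @param tau2 nugget (noise variance, > 0).
#' @param phi range in km (> 0); correlation is exactly 0 beyond it.
#' @param seed integer seed.
#' @return numeric vector of length `nrow(geometry)`.
#' @export
gen_gp_field <- function(geometry, beta0, sigma2, tau2, phi, seed = 1) {
  assert_scalar_number(sigma2, "sigma2", positive = TRUE)
  assert_scalar_number(tau2, "tau2", positive = TRUE)
  assert_scalar_number(phi, "phi", positive = TRUE)
  n <- nrow(geometry)
  D <- distance_matrix(geometry$x_km, geometry$y_km)
  H <- spherical_correlation(D, phi)
  Sigma <- sigma2 * H + diag(tau2, n)
  set.seed(as.integer(seed))
  L <- chol_psd(Sigma)
  as.numeric(beta0 + crossprod(L, stats::rnorm(n)))
}

# upper-triangular Cholesky with a small diagonal jitter fallback
chol_psd <- function(S, jitter = 1e-8) {
  tryCatch(chol(S), error = function(e) {
    warning("covariance nearly singular; adding diagonal jitter ", jitter)
    chol(S + diag(jitter, nrow(S)))
  })
}
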