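#' k-nearest-neighbour spatial weights
#'
#' Builds an n x n weight matrix from unit centroids: each row has its `k`
#' nearest neighbours (Euclidean distance in km) set to 1, optionally
#' row-standardized to sum to 1. Distance ties are broken deterministically
#' by lexicographic `unit_id` order (with a warning when coordinates
#' coincide). The diagonal is always zero. Contiguity ("queen") weights
#' require polygon geometry and are not supported for centroid input.
#'
#' @param geometry data.frame with `unit_id`, `x_km`, `y_km`.
#' @param scheme only `"knn"` is supported.
#' @param k number of neighbours (1 <= k <= n-1).
#' @param row_standardize divide each row by its sum (default `TRUE`).
#' @return object of class `spatial_weights`: list with dense matrix `W`
#'   (dimnames = unit ids), `ids`, `scheme`, `k`, `row_standardized`.
#' @export
build_weights <- function(geometry, scheme = c("knn", "contiguity"), k = 8,
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "contiguity")
    stop_invalid("contiguity weights require polygon geometry, which is not supported; use scheme = 'knn' on centroids")
  n <- nrow(geometry)
  if (anyDuplicated(geometry$unit_id)) stop_invalid("unit_ids must be unique")
  if (!is.numeric(k) || k < 1 || k >= n)
    stop_invalid("k must satisfy 1 <= k <= n - 1 (n = ", n, ")")
  k <- as.integer(k)
  D <- distance_matrix(geometry$x_km, geometry$y_km)
  diag(D) <- Inf
  if (any(D[upper.tri(D)] == 0))
    warning("duplicate coordinates; k-NN ties broken by unit_id order")
  id_rank <- rank(geometry$unit_id, ties.method = "first")
  W <- matrix(0, n, n, dimnames = list(geometry$unit_id, geometry$unit_id))
  for (i in seq_len(n)) {
    nb <- order(D[i, ], id_rank)[seq_len(k)]
    W[i, nb] <- 1
  }
  if (row_standardize) W <- W / rowSums(W)
  structure(list(W = W, ids = geometry$unit_id, scheme = scheme, k = k,
                 row_standardized = isTRUE(row_standardize)),
            class = "spatial_weights")
}

# align a value vector with a weights object, reordered by sorted unit id so
# permutation inference is invariant to input row order/relabeling
align_sorted <- function(x, weights) {
  ids <- weights$ids
  if (!is.null(names(x))) {
    if (!setequal(names(x), ids)) stop_invalid("names(x) do not match weights ids")
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop_invalid("x must have one value per unit (", length(ids), ")")
  }
  o <- order(ids)
  list(x = as.numeric(x)[o], W = weights$W[o, o, drop = FALSE], ids = ids[o],
       unsort = order(o))
}

moran_I_stat <- function(z, W, S0) {
  length(z) / S0 * sum(z * (W %*% z)) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Inference is by random permutation of the values over locations with the
#' +1-corrected pseudo p-value
#' `p = (1 + #extreme) / (1 + n_permutations)`; "extreme" compares
#' `|I* - E[I]|` to `|I - E[I]|` for the two-sided default, with one-sided
#' options. `E[I] = -1/(n-1)` under randomization. The permutation stream is
#' aligned to units sorted by id, so results are invariant to input row
#' order.
#'
#' @param x per-unit values (named by unit id, or in weights order).
#' @param weights a [build_weights()] object.
#' @param n_permutations permutation count (default 999).
#' @param seed integer seed for the permutation draw.
#' @param alpha significance level for the verdict.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return object of class `moran_result`: `I`, `expected_I`, `z_perm`,
#'   `p_perm`, `n_permutations`, `alpha`, `alternative`, `verdict`
#'   ("clustered", "dispersed" or "random").
#' @export
global_moran <- function(x, weights, n_permutations = 999, seed = 1,
                         alpha = 0.05,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(weights, "spatial_weights"))
  a <- align_sorted(x, weights)
  n <- length(a$x)
  if (n < 4) stop_invalid("need at least 4 units")
  if (stats::var(a$x) == 0)
    stop(errorCondition("x has zero variance; Moran's I undefined",
                        class = c("firexcess_degenerate_variance", "error")))
  z <- a$x - mean(a$x)
  S0 <- sum(a$W)
  I <- moran_I_stat(z, a$W, S0)
  EI <- -1 / (n - 1)
  set.seed(as.integer(seed))
  P <- matrix(0, n, n_permutations)
  for (b in seq_len(n_permutations)) P[, b] <- z[sample.int(n)]
  Istar <- (n / S0) * colSums(P * (a$W %*% P)) / sum(z^2)
  extreme <- switch(alternative,
    two.sided = abs(Istar - EI) >= abs(I - EI),
    greater   = Istar >= I,
    less      = Istar <= I)
  p <- (1 + sum(extreme)) / (1 + n_permutations)
  verdict <- if (p > alpha) "random" else if (I > EI) "clustered" else "dispersed"
  structure(list(I = I, expected_I = EI,
                 z_perm = (I - mean(Istar)) / stats::sd(Istar),
                 p_perm = p, n_permutations = as.integer(n_permutations),
                 alpha = alpha, alternative = alternative, verdict = verdict),
            class = "moran_result")
}

#' Anselin Local Moran's I with conditional permutation inference
#'
#' `I_i = ((x_i - xbar)/m2) * sum_j w_ij (x_j - xbar)` with
#' `m2 = sum_k (x_k - xbar)^2 / n`. Each unit is classified into the LISA
#' quadrant (HH, LL, HL, LH) by the signs of its own deviation and of its
#' spatial lag's deviation. p-values use conditional permutation: `x_i` is
#' held fixed while the remaining values are permuted among the other
#' locations; the +1-corrected pseudo p is two-sided by default (distance
#' from the permutation mean), with a one-sided `"greater"` option
#' emphasizing high-high clustering.
#'
#' @inheritParams global_moran
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across units.
#' @return object of class `local_moran_result`: data.frame `table` with
#'   unit_id, I_i, quadrant, p, p_adj, significant, plus fields `I_sum`,
#'   `alpha`, `n_permutations`.
#' @export
local_moran <- function(x, weights, n_permutations = 999, seed = 1,
                        alpha = 0.05,
                        alternative = c("two.sided", "greater"),
                        p_adjust = c("none", "BH")) {
  alternative <- match.arg(alternative)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(weights, "spatial_weights"))
  a <- align_sorted(x, weights)
  n <- length(a$x)
  if (n < 4) stop_invalid("need at least 4 units")
  if (stats::var(a$x) == 0)
    stop(errorCondition("x has zero variance; Local Moran's I undefined",
                        class = c("firexcess_degenerate_variance", "error")))
  z <- a$x - mean(a$x)
  m2 <- sum(z^2) / n
  lag <- as.numeric(a$W %*% z)
  Ii <- z / m2 * lag
  quadrant <- rep(NA_character_, n)
  nz <- z != 0
  quadrant[nz] <- ifelse(z[nz] > 0,
                         ifelse(lag[nz] >= 0, "HH", "HL"),
                         ifelse(lag[nz] >= 0, "LH", "LL"))
  set.seed(as.integer(seed))
  p <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a$W[i, ] != 0)
    wnb <- a$W[i, nb]
    pool <- z[-i]
    k <- length(nb)
    idx <- matrix(0L, k, n_permutations)
    for (b in seq_len(n_permutations)) idx[, b] <- sample.int(n - 1L, k)
    lag_star <- colSums(wnb * matrix(pool[idx], k))
    Istar <- z[i] / m2 * lag_star
    extreme <- switch(alternative,
      two.sided = abs(Istar - mean(Istar)) >= abs(Ii[i] - mean(Istar)),
      greater   = Istar >= Ii[i])
    p[i] <- (1 + sum(extreme)) / (1 + n_permutations)
  }
  p_adj <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  tab <- data.frame(unit_id = a$ids, I_i = Ii, quadrant = quadrant,
                    p = p, p_adj = p_adj, significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  tab <- tab[a$unsort, ]
  rownames(tab) <- NULL
  structure(list(table = tab, I_sum = sum(Ii), alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 alternative = alternative, p_adjust = p_adjust),
            class = "local_moran_result")
}

#' Global Moran's I over multiple analysis periods
#'
#' Runs [global_moran()] on the per-unit excess of each period (fire and
#' falsification alike) and tabulates the verdicts. The scientific
#' expectation is a contrast: wildfire periods cluster, no-fire
#' (falsification) periods come out "random".
#'
#' @param excess_by_period named list of per-unit value vectors.
#' @param weights a [build_weights()] object.
#' @param n_permutations,seed,alpha,alternative passed to [global_moran()].
#' @return data.frame with one row per period: period, I, z_perm, p_perm,
#'   verdict.
#' @export
falsification_report <- function(excess_by_period, weights,
                                 n_permutations = 999, seed = 1, alpha = 0.05,
                                 alternative = "two.sided") {
  stopifnot(length(excess_by_period) >= 1)
  if (is.null(names(excess_by_period)))
    names(excess_by_period) <- paste0("period_", seq_along(excess_by_period))
  rows <- lapply(names(excess_by_period), function(nm) {
    m <- global_moran(excess_by_period[[nm]], weights,
                      n_permutations = n_permutations, seed = seed,
                      alpha = alpha, alternative = alternative)
    data.frame(period = nm, I = m$I, expected_I = m$expected_I,
               z_perm = m$z_perm, p_perm = m$p_perm, verdict = m$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), pseudo p = %.4f [%s] -> %s\n",
              x$I, x$expected_I, x$p_perm, x$alternative, x$verdict))
  invisible(x)
}

#' @export
print.local_moran_result <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  cat("Local Moran's I:", nrow(x$table), "units,",
      nrow(sig), "significant at alpha =", x$alpha, "\n")
  if (nrow(sig)) print(utils::head(sig, 10))
  invisible(x)
}
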