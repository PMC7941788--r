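# Multilevel B-spline approximation (MBA) of scattered data: a hierarchy of
# progressively finer uniform cubic B-spline control lattices, each fitted
# (by the local least-squares "BA" update) to the residuals left by the
# coarser levels. A least-squares plane is removed first and added back on
# evaluation, so constant and affine inputs are reproduced exactly.

# uniform cubic B-spline basis values B_0..B_3 at local parameter t in [0,1)
bspline_basis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# sparse-free dense basis matrix: rows = points, cols = m + 3 control points
# for a lattice with m cells over [0, m] in lattice units
basis_matrix <- function(u, m) {
  i <- pmin(floor(u), m - 1)          # cell index 0..m-1
  t <- u - i
  B <- bspline_basis(t)
  out <- matrix(0, length(u), m + 3)
  for (k in 0:3) out[cbind(seq_along(u), i + k + 1)] <- B[, k + 1]
  out
}

# one BA fit: control lattice (m+3) x (n+3) approximating residuals r at
# lattice coordinates (u, v) in [0, m] x [0, n]
ba_fit <- function(u, v, r, m, n) {
  Bu <- basis_matrix(u, m)            # npts x (m+3)
  Bv <- basis_matrix(v, n)            # npts x (n+3)
  num <- matrix(0, m + 3, n + 3)
  den <- matrix(0, m + 3, n + 3)
  for (p in seq_along(r)) {
    w <- tcrossprod(Bu[p, ], Bv[p, ]) # (m+3) x (n+3), mostly zero
    sw2 <- sum(w^2)
    if (sw2 == 0) next
    num <- num + w^2 * (w * r[p] / sw2)
    den <- den + w^2
  }
  phi <- num / den
  phi[den == 0] <- 0
  phi
}

eval_lattice_points <- function(phi, u, v) {
  m <- nrow(phi) - 3L; n <- ncol(phi) - 3L
  Bu <- basis_matrix(u, m)
  Bv <- basis_matrix(v, n)
  rowSums((Bu %*% phi) * Bv)
}

#' Multilevel B-spline interpolated surface on a raster grid
#'
#' Fits a coarse-to-fine hierarchy of cubic B-spline control lattices to
#' scattered per-unit values (the classic multilevel B-spline approximation
#' for scattered data): level 1 uses a single-cell lattice, and each
#' subsequent level doubles the lattice resolution and is fitted to the
#' residuals of the accumulated surface, so the data-point residual shrinks
#' as levels increase. A least-squares plane is removed before the lattice
#' fit and restored on evaluation. The surface is evaluated on a
#' `grid_n x grid_n` raster over the (square, padded) data extent.
#'
#' @param values per-unit values to interpolate.
#' @param coords matrix/data.frame of planar (x, y) km coordinates.
#' @param grid_n raster dimension (default 300, i.e. a 300 x 300 grid).
#' @param levels number of refinement levels (default 7).
#' @param pad fractional extent padding before squaring (default 0.05).
#' @return object of class `grid_surface`: `z` (`grid_n x grid_n` matrix,
#'   rows = x index, cols = y index), `x`, `y` (cell-centre coordinates),
#'   `bbox` (xmin, ymin, xmax, ymax), `cellsize`, and `rms_by_level`
#'   (data-point RMS residual after each level).
#' @export
interpolate_surface <- function(values, coords, grid_n = 300, levels = 7,
                                pad = 0.05) {
  if (!is.numeric(grid_n) || grid_n < 2) stop_invalid("grid_n must be >= 2")
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  z <- as.numeric(values)
  if (length(z) < 4) stop_invalid("need >= 4 data points")
  if (qr(cbind(1, coords))$rank < 3)
    stop_invalid("data points are collinear; surface fit is degenerate")
  grid_n <- as.integer(grid_n)

  # square, padded extent so raster cells are square (ESRI ASCII needs one
  # cellsize)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  side <- max(diff(rx), diff(ry)) * (1 + 2 * pad)
  cx <- mean(rx); cy <- mean(ry)
  bbox <- c(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
  cell <- side / grid_n

  # affine trend (exact for constant/affine inputs)
  X <- cbind(1, coords)
  tr <- qr.coef(qr(X), z)
  resid <- z - as.numeric(X %*% tr)

  # lattice coordinates in [0, m]
  ux <- (coords[, 1] - bbox[1]) / side
  uy <- (coords[, 2] - bbox[2]) / side
  gx <- bbox[1] + (seq_len(grid_n) - 0.5) * cell
  gy <- bbox[2] + (seq_len(grid_n) - 0.5) * cell
  gux <- (gx - bbox[1]) / side
  guy <- (gy - bbox[2]) / side

  zsurf <- matrix(0, grid_n, grid_n)
  rms <- numeric(levels)
  m <- 1L
  for (lev in seq_len(levels)) {
    phi <- ba_fit(ux * m, uy * m, resid, m, m)
    resid <- resid - eval_lattice_points(phi, ux * m, uy * m)
    rms[lev] <- sqrt(mean(resid^2))
    Bgx <- basis_matrix(gux * m, m)
    Bgy <- basis_matrix(guy * m, m)
    zsurf <- zsurf + Bgx %*% phi %*% t(Bgy)
    m <- m * 2L
  }
  zsurf <- zsurf + outer(gx, gy, function(a, b) tr[1] + tr[2] * a + tr[3] * b)

  structure(list(z = zsurf, x = gx, y = gy, bbox = bbox, cellsize = cell,
                 rms_by_level = rms, levels = levels),
            class = "grid_surface")
}

#' Write a grid surface as an ESRI ASCII raster
#'
#' @param surface a [interpolate_surface()] result.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(surface, path) {
  stopifnot(inherits(surface, "grid_surface"))
  nr <- length(surface$y); nc <- length(surface$x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(surface$bbox[1], digits = 12)),
    paste("yllcorner", format(surface$bbox[2], digits = 12)),
    paste("cellsize", format(surface$cellsize, digits = 12)),
    "NODATA_value -9999"
  ), con)
  # ESRI rows run north -> south; z is [x, y]
  for (j in rev(seq_len(nr)))
    writeLines(paste(format(surface$z[, j], digits = 8), collapse = " "), con)
  invisible(path)
}
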