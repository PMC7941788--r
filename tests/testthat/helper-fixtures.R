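# fixtures and independent brute-force oracles used across tests

# geometry with units on a line at x = 0..(n-1), y = 0
line_geometry <- function(n) {
  data.frame(unit_id = sprintf("L%02d", seq_len(n)),
             x_km = as.numeric(seq_len(n) - 1), y_km = 0,
             population = 100L, stringsAsFactors = FALSE)
}

square_geometry <- function() {
  data.frame(unit_id = c("A", "B", "C", "D"),
             x_km = c(0, 1, 1, 0), y_km = c(0, 0, 1, 1),
             population = 100L, stringsAsFactors = FALSE)
}

random_geometry <- function(n, seed) {
  set.seed(seed)
  data.frame(unit_id = sprintf("R%02d", seq_len(n)),
             x_km = runif(n, 0, 50), y_km = runif(n, 0, 50),
             population = 100L, stringsAsFactors = FALSE)
}

# O(n^2) double-loop Moran's I, independent of the package implementation
brute_global_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# brute-force Local Moran's I_i
brute_local_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + W[i, j] * z[j]
    out[i] <- z[i] / m2 * acc
  }
  out
}

# build a complete constant-rate panel over a date span
constant_panel <- function(units, dates, count = 2L) {
  expand.grid(unit_id = units, date = dates, stringsAsFactors = FALSE) |>
    transform(count = count)
}
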