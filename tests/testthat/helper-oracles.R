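# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Otsu oracle: bin exactly as the contract states (n_bins equal-width bins
# over [min, max]), then exhaustively evaluate the between-class variance of
# every interior bin-edge cut directly from the raw values, returning the
# smallest maximizing edge.
oracle_otsu <- function(values, n_bins = 256L) {
  mn <- min(values); mx <- max(values)
  if (mx <= mn) return(mn)
  idx <- pmin(n_bins, floor((values - mn) / (mx - mn) * n_bins) + 1L)
  best_k <- NA_integer_
  best <- -Inf
  N <- length(values)
  for (k in seq_len(n_bins - 1L)) {
    lower <- values[idx <= k]
    upper <- values[idx > k]
    if (length(lower) == 0 || length(upper) == 0) next
    w0 <- length(lower) / N
    sb <- w0 * (1 - w0) * (mean(lower) - mean(upper))^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  mn + best_k * (mx - mn) / n_bins
}

# Circular runs oracle: walk every index of a logical circle, detect run
# starts by direct neighbour comparison, extend element by element.
oracle_circular_runs <- function(above, spacing_um) {
  n <- length(above)
  if (all(above)) return(list(n_crossings = 0L, run_lengths_um = n * spacing_um))
  if (!any(above)) return(list(n_crossings = 0L, run_lengths_um = numeric(0)))
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (above[i] != above[j]) crossings <- crossings + 1L
  }
  runs <- numeric(0)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    if (above[i] && !above[prev]) {  # run starts at i
      len <- 0L
      j <- i
      while (above[j]) {
        len <- len + 1L
        j <- if (j == n) 1L else j + 1L
      }
      runs <- c(runs, len * spacing_um)
    }
  }
  list(n_crossings = crossings, run_lengths_um = runs)
}

# Small synthetic pair used across tests: constant-intensity channels.
make_constant_pair <- function(size = 64L, g_val = 100, r_val = 50,
                               pixel_size_um = 10) {
  ctr <- (size + 1) / 2
  colony_image_pair(
    channel_image(matrix(g_val, size, size), 8L, pixel_size_um, "green"),
    channel_image(matrix(r_val, size, size), 8L, pixel_size_um, "red"),
    c(ctr, ctr), 50)
}
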