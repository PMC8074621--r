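# shared fixtures and independent oracles

# spatial_weights from a dense binary adjacency matrix
weights_from_matrix <- function(W, ids = as.character(seq_len(nrow(W)))) {
  idx <- which(W == 1, arr.ind = TRUE)
  reportlag:::new_spatial_weights(ids, data.frame(from = idx[, 1], to = idx[, 2]),
                                  "custom", isSymmetric(W))
}

# brute-force double-sum oracles for Moran's I (independent of the package's
# sparse-matrix implementation)
bf_global_moran <- function(v, W) {
  m <- length(v); z <- v - mean(v)
  (m / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

bf_local_moran <- function(v, W) {
  m <- length(v); z <- v - mean(v)
  vapply(seq_len(m), function(j) {
    (m - 1) * z[j] / sum(z[-j]^2) * sum(W[j, ] * z)
  }, numeric(1))
}

# random symmetric binary adjacency with no self-links
random_adjacency <- function(m, p = 0.3) {
  W <- matrix(rbinom(m * m, 1, p), m, m)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  if (all(W == 0)) W[1, 2] <- W[2, 1] <- 1
  W
}

unit_square_grid <- function(nx, ny) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  lapply(seq_len(nrow(g)), function(i) {
    cbind(c(0, 1, 1, 0) + g$x[i], c(0, 0, 1, 1) + g$y[i])
  })
}

# minimal event table
toy_events <- function(delays, districts = rep("A", length(delays)),
                       start = as.Date("2015-06-01")) {
  occ <- start + seq_along(delays) - 1
  data.frame(id = seq_along(delays), occurrence_date = occ,
             report_date = occ + delays, district_id = districts,
             delay_days = as.integer(delays),
             binarize_delay(delays), log_delay = log_delay(delays))
}
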