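# Independent brute-force oracles used across the suite. These deliberately
# use plain double loops / direct formulas, never the package's fast paths.

# O(N * L) fluorescence autocorrelation: G(k) = mean_t x[t] x[t+k] / mean(x)^2
brute_force_G <- function(x, lag_steps) {
  n <- length(x)
  mu <- mean(x)
  vapply(lag_steps, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + x[t] * x[t + k]
    (s / (n - k)) / mu^2
  }, numeric(1L))
}

# brute-force intermittent / continuous H-bond existence correlation
brute_force_C <- function(h, lag_steps, continuous = FALSE) {
  n <- nrow(h); nb <- ncol(h)
  vapply(lag_steps, function(k) {
    num <- 0; den <- 0
    for (b in seq_len(nb)) {
      for (t in seq_len(n - k)) {
        if (h[t, b] == 1L) {
          den <- den + 1
          ok <- if (continuous) all(h[t:(t + k), b] == 1L) else h[t + k, b] == 1L
          if (ok) num <- num + 1
        }
      }
    }
    num / den
  }, numeric(1L))
}

# direct Monte-Carlo of a freely jointed chain's squared end-to-end distance
random_walk_r2 <- function(n_beads, bond_length, n_walks) {
  r2 <- numeric(n_walks)
  for (w in seq_len(n_walks)) {
    v <- matrix(rnorm(3L * (n_beads - 1L)), ncol = 3L)
    v <- v / sqrt(rowSums(v^2))
    e <- colSums(v) * bond_length
    r2[w] <- sum(e^2)
  }
  mean(r2)
}

# exhaustive pairwise minimum distance between two coordinate matrices
brute_force_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# quick structure: a row of atoms at given coordinates (nm)
atoms_at <- function(xyz, names = rep("CA", nrow(xyz)),
                     residues = seq_len(nrow(xyz))) {
  structure_from_atoms(data.frame(
    atom_name = names, element = substr(names, 1L, 1L),
    residue_index = residues, residue_name = "GLY", chain_id = "A",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], stringsAsFactors = FALSE))
}

# analytic two-state Markov conditional survival:
# P(open at t | open at 0) = p + (1 - p) * exp(-(kc + ko) t)
markov_G <- function(tau, k_close, k_open) {
  p <- k_open / (k_close + k_open)
  (p + (1 - p) * exp(-(k_close + k_open) * tau)) / p
}
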