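# Small family models and simulation configs shared across tests, plus
# independent brute-force oracles.

small_families <- function(seed = 5, ltr = c(100, 80), internal = c(800, 300)) {
  fams <- default_families(seed, ltr, internal)
  fams$famA$size_windows <- matrix(c(2 * ltr[1] + internal[1] - 50,
                                     2 * ltr[1] + internal[1] + 50), 1)
  fams$famB$size_windows <- matrix(c(2 * ltr[2] + internal[2] - 50,
                                     2 * ltr[2] + internal[2] + 50), 1)
  fams
}

small_sim_config <- function(seed = 11, copies = 15, genome = 6e5, ...) {
  sim_config(genome_length = genome, copies_per_family = copies,
             families = small_families(),
             decoy_solo_ltrs = 2, decoy_truncated = 2, decoy_recombinant = 2,
             seed = seed, ...)
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Independent affine-gap Smith-Waterman (Gotoh) oracle for short sequences.
sw_oracle <- function(a, b, match = 5, mismatch = -4, gap_open = 10,
                      gap_extend = 0.5) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  H <- matrix(0, n + 1, m + 1)   # best ending in match/mismatch or fresh start
  E <- matrix(-Inf, n + 1, m + 1) # gap in b (deletion from a)
  F <- matrix(-Inf, n + 1, m + 1) # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     E[i - 1, j] - gap_extend)
      F[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     F[i, j - 1] - gap_extend)
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force per-base hot-spot oracle: maximal runs of bases satisfying both
# fold conditions inside the regions.
hotspot_oracle <- function(depth, control_sum, mask, baseline, fold = 5,
                           min_len = 100) {
  ok <- logical(length(depth))
  for (i in seq_along(depth)) {
    ok[i] <- mask[i] && depth[i] >= fold * baseline &&
      depth[i] >= fold * control_sum[i]
  }
  runs <- list()
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# All permutations of 1..n as rows of a matrix (tiny n only).
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
}

# Independent closed-form K2P evaluation (different algebraic arrangement).
k2p_oracle <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}
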