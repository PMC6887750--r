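# Independent oracles and fixture builders shared across the suite.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# Plain-R Gotoh local-alignment score, written independently of the
# package's C++ path. Gap of length k costs gap_open + k * gap_extend.
sw_oracle_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                             E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                             F[i, j + 1] + gap_extend)
      sub <- if (qc[i] == sc[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sub,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Pearson chi-square by the direct sum over cells.
chisq_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Small burst fixture used by several files.
small_burst <- function(seed = 1, n_full = 50, n_der = 60,
                        fragmentation_prob = 0.3, genome_length = 3e5,
                        age_mean = 86e6, age_sd = 10e6, rate_s = 2.2e-9,
                        master_seed = 1) {
  master <- make_master(865, 24, c(300, 561), seed = master_seed)
  sim <- simulate_burst(
    master,
    burst_model(rate_s = rate_s, age_mean = age_mean, age_sd = age_sd,
                n_copies = c(full = n_full, deletion_derivative = n_der),
                fragmentation_prob = fragmentation_prob, seed = seed),
    genome_length = genome_length)
  sim
}

# Minimal-chain-count oracle: enumerate every assignment of hits (in
# genomic order) to admissible chains; admissibility mirrors the
# documented chaining rule.
chain_oracle_min_chains <- function(hits, max_gap_bp = 500,
                                    max_query_overlap_bp = 20) {
  o <- order(hits$target_id, hits$strand, hits$query_id,
             hits$target_start, hits$target_end)
  h <- hits[o, , drop = FALSE]
  n <- nrow(h)
  admissible <- function(last, nxt) {
    if (h$target_id[last] != h$target_id[nxt] ||
        h$strand[last] != h$strand[nxt] ||
        h$query_id[last] != h$query_id[nxt]) return(FALSE)
    gap <- h$target_start[nxt] - h$target_end[last]
    if (gap > max_gap_bp || gap < -max_query_overlap_bp) return(FALSE)
    if (h$strand[nxt] == "+") {
      h$query_start[nxt] >= h$query_end[last] - max_query_overlap_bp &&
        h$query_start[nxt] >= h$query_start[last]
    } else {
      h$query_end[nxt] <= h$query_start[last] + max_query_overlap_bp &&
        h$query_end[nxt] <= h$query_end[last]
    }
  }
  best <- n
  recurse <- function(i, chain_tails) {
    if (length(chain_tails) >= best) return()
    if (i > n) {
      best <<- min(best, length(chain_tails))
      return()
    }
    for (ci in seq_along(chain_tails)) {
      if (admissible(chain_tails[ci], i)) {
        tails <- chain_tails
        tails[ci] <- i
        recurse(i + 1, tails)
      }
    }
    recurse(i + 1, c(chain_tails, i))
  }
  recurse(2L, 1L)
  if (n == 0L) 0L else best
}
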