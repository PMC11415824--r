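# Independent oracles used to freeze expected values. These are written as
# plain, slow reference implementations and must stay independent of the
# package's own code paths.

# Unbanded affine-gap local alignment score, pure R triple-loop.
# Gap of length L costs gap_open + L * gap_extend. N scores 0, never a match.
oracle_sw_score <- function(q, t, match = 2, mismatch = -4, gap_open = -4,
                            gap_extend = -2) {
  qc <- strsplit(toupper(q), "")[[1]]
  tc <- strsplit(toupper(t), "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (qc[i - 1] == "N" || tc[j - 1] == "N") 0
      else if (qc[i - 1] == tc[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# character-by-character reverse complement, independent of Biostrings
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# best-of-both-strands score using the oracle
oracle_sw_both <- function(q, t, ...) {
  max(oracle_sw_score(q, t, ...), oracle_sw_score(oracle_revcomp(q), t, ...))
}

# independent re-statement of the chaining rule, written as an explicit
# one-pass loop over the sorted signatures
oracle_chain_clusters <- function(pos, len, max_distance, size_ratio) {
  stopifnot(!is.unsorted(pos))
  assignment <- integer(length(pos))
  cluster <- 1L
  members <- 1L
  assignment[1] <- 1L
  for (i in seq_along(pos)[-1]) {
    med <- median(len[members])
    ratio <- min(len[i], med) / max(len[i], med)
    if (pos[i] - pos[members[length(members)]] <= max_distance &&
        ratio >= size_ratio) {
      members <- c(members, i)
    } else {
      cluster <- cluster + 1L
      members <- i
    }
    assignment[i] <- cluster
  }
  assignment
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutate a sequence with substitutions at the given rate
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
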