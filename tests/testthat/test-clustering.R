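sig_df <- function(pos, len, svtype = "INS", read = NULL) {
  n <- length(pos)
  if (is.null(read)) read <- paste0("r", seq_len(n))
  data.frame(chrom = "simchr1", pos = as.integer(pos), svtype = svtype,
             length = as.integer(len),
             inserted_sequence = ifelse(svtype == "INS",
                                        vapply(len, function(l)
                                          strrep("A", l), character(1)), ""),
             read_name = read, source = "cigar", stringsAsFactors = FALSE)
}

test_that("chaining rule: the worked examples", {
  cfg1 <- caller_config(min_support = 1L)
  # one signature -> one cluster of support 1
  cl <- cluster_signatures(sig_df(100, 300), cfg1)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$support, 1L)

  # two INS 10 bp apart, lengths 300/310 -> one cluster of support 2
  cl <- cluster_signatures(sig_df(c(100, 110), c(300, 310)), cfg1)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$support, 2L)
  expect_equal(cl[[1]]$anchor_pos, 105L)

  # 5000 bp apart -> two clusters; with min_support 2 -> zero survive
  cl <- cluster_signatures(sig_df(c(100, 5100), c(300, 300)), cfg1)
  expect_length(cl, 2L)
  expect_length(cluster_signatures(sig_df(c(100, 5100), c(300, 300)),
                                   caller_config(min_support = 2L)), 0L)

  # same pos, lengths 300 vs 4000: size ratio fails -> two clusters
  cl <- cluster_signatures(sig_df(c(100, 100), c(300, 4000)), cfg1)
  expect_length(cl, 2L)
})

test_that("chaining agrees with the independent oracle on random cases", {
  cfg1 <- caller_config(min_support = 1L)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    pos <- sort(sample(1:20000, n))
    len <- sample(c(50:80, 280:320, 900:1000), n, replace = TRUE)
    cl <- cluster_signatures(sig_df(pos, len), cfg1)
    oracle <- oracle_chain_clusters(pos, len, cfg1$cluster_max_distance,
                                    cfg1$cluster_size_ratio)
    # same number of clusters and same member partition
    expect_length(cl, max(oracle))
    got <- unlist(lapply(seq_along(cl), function(i)
      rep(i, nrow(cl[[i]]$members))))
    # clusters are ordered by anchor; map both to canonical form
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(oracle, levels = unique(oracle))))
  }
})

test_that("clustering partitions the input and ignores shuffling", {
  cfg1 <- caller_config(min_support = 1L)
  set.seed(5)
  pos <- sort(sample(1:50000, 30))
  len <- sample(250:350, 30, replace = TRUE)
  s <- sig_df(pos, len)
  cl <- cluster_signatures(s, cfg1)
  expect_equal(sum(vapply(cl, function(c) nrow(c$members), integer(1))),
               nrow(s))
  # shuffled input gives identical clusters
  s2 <- s[sample(nrow(s)), , drop = FALSE]
  cl2 <- cluster_signatures(s2, cfg1)
  expect_equal(lapply(cl, function(c) c$members$read_name),
               lapply(cl2, function(c) c$members$read_name))

  # mixed chromosomes are refused
  s3 <- s
  s3$chrom[1] <- "chr2"
  expect_error(cluster_signatures(s3, cfg1), "single chromosome")
})

test_that("INS consensus: unanimity, single member, majority column", {
  cfg <- caller_config()
  mk_cluster <- function(seqs) {
    m <- sig_df(rep(100, length(seqs)), nchar(seqs))
    m$inserted_sequence <- seqs
    list(chrom = "simchr1", svtype = "INS", members = m,
         anchor_pos = 100L, median_length = as.integer(median(nchar(seqs))),
         support = length(seqs))
  }
  # unanimity
  cc <- build_consensus(mk_cluster(rep("ACGTACGT", 3)), cfg = cfg)
  expect_identical(cc$consensus_sequence, "ACGTACGT")
  # single member verbatim
  cc <- build_consensus(mk_cluster("ACGTTT"), cfg = cfg)
  expect_identical(cc$consensus_sequence, "ACGTTT")

  # 3 x 100 bp, one sequence substituted at position 50: majority wins
  set.seed(9)
  base <- random_dna(100)
  mut <- base
  old <- substring(mut, 50, 50)
  substring(mut, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  cc <- build_consensus(mk_cluster(c(base, base, mut)), cfg = cfg)
  expect_identical(cc$consensus_sequence, base)

  # exhaustive column-majority oracle over several random column patterns
  for (rep in 1:10) {
    s0 <- random_dna(60)
    seqs <- c(s0, s0, s0)
    k <- sample(1:60, 5)
    for (p in k) {
      i <- sample(1:3, 1)
      substring(seqs[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    cc <- build_consensus(mk_cluster(seqs), cfg = cfg)
    chars <- do.call(rbind, strsplit(seqs, ""))
    oracle <- paste(apply(chars, 2, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      names(tab)[which.max(tab)]  # alphabetical tie-break
    }), collapse = "")
    expect_identical(cc$consensus_sequence, oracle)
  }
})

test_that("consensus length stays near the member length range", {
  d <- local_small_dataset()
  cfg <- caller_config(min_support = 3L)
  out <- scan_alignments(d$sam, cfg = cfg)
  cl <- cluster_signatures(out$signatures[out$signatures$svtype == "INS", ],
                           cfg)
  ref <- load_reference(d$ref)
  for (c in cl) {
    cc <- build_consensus(c, ref, cfg)
    lo <- min(c$members$length) * 0.9
    hi <- max(c$members$length) * 1.1
    expect_gte(cc$consensus_length, lo)
    expect_lte(cc$consensus_length, hi)
  }
})

test_that("DEL consensus is the reference interval; bounds are checked", {
  ref <- c(simchr1 = "ACGTACGTACGTACGTACGT")
  m <- sig_df(8, 4, svtype = "DEL")
  cl <- list(chrom = "simchr1", svtype = "DEL", members = m, anchor_pos = 8L,
             median_length = 4L, support = 1L)
  cc <- build_consensus(cl, ref)
  expect_identical(cc$consensus_sequence, substring(ref[[1]], 9, 12))

  cl$anchor_pos <- 19L
  expect_error(build_consensus(cl, ref), "outside reference")
  expect_error(build_consensus(cl, NULL), "requires the reference")
})
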