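test_that("no events means identical haplotypes and empty truth", {
  p <- sim_params(genome_length = 120000L, n_mei_per_class = 0L,
                  n_med_per_class = 0L, n_ordinary_sv = 0L, seed = 3L)
  sim <- simulate_genome(p)
  expect_identical(sim$hap1$seq, sim$reference[[1]])
  expect_identical(sim$hap2$seq, sim$reference[[1]])
  expect_equal(nrow(sim$truth), 0L)
})

test_that("length bookkeeping for homozygous insertions", {
  p <- sim_params(genome_length = 120000L, n_mei_per_class = 1L,
                  n_med_per_class = 0L, n_ordinary_sv = 0L,
                  het_fraction = 0, seed = 4L)
  sim <- simulate_genome(p)
  tr <- sim$truth
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$gt == "1|1"))
  expect_true(all(tr$svtype == "INS"))
  expect_equal(nchar(sim$hap1$seq), nchar(sim$reference[[1]]) + sum(tr$svlen))
  expect_identical(sim$hap1$seq, sim$hap2$seq)
  # inserted sequences actually sit in the haplotype
  for (s in tr$seq) expect_match(sim$hap1$seq, s, fixed = TRUE)

  # a library missing a requested class is refused
  alu_only <- builtin_me_library()
  alu_only$templates <- alu_only$templates[alu_only$templates$me_class == "Alu", ]
  expect_error(simulate_genome(p, alu_only), "no template of class")
})

test_that("truth record count equals the event bookkeeping identity", {
  p <- small_sim_params(seed = 5L)
  sim <- simulate_genome(p)
  expect_equal(nrow(sim$truth),
               3L * p$n_mei_per_class + 3L * p$n_med_per_class +
                 p$n_ordinary_sv)
  expect_true(all(sim$truth$me_class[abs(sim$truth$svlen) >= 50 &
                                       sim$truth$me_class != "none"] %in%
                    c("Alu", "L1", "SVA")))
  # MEDs embed element content in the reference
  med <- sim$truth[sim$truth$svtype == "DEL" & sim$truth$me_class != "none", ]
  ref <- sim$reference[[1]]
  for (i in seq_len(nrow(med))) {
    expect_identical(substring(ref, med$pos[i] + 1L,
                               med$pos[i] + abs(med$svlen[i])), med$seq[i])
  }
})

test_that("same seed gives byte-identical outputs, different seed differs", {
  p <- sim_params(genome_length = 120000L, n_mei_per_class = 1L,
                  n_med_per_class = 1L, n_ordinary_sv = 2L, depth = 5,
                  seed = 6L)
  d1 <- simulate_dataset(p, out_dir = tempfile())
  d2 <- simulate_dataset(p, out_dir = tempfile())
  expect_identical(readLines(d1$ref), readLines(d2$ref))
  expect_identical(readLines(d1$truth_vcf), readLines(d2$truth_vcf))
  expect_identical(readLines(d1$sam), readLines(d2$sam))
  p3 <- p; p3$seed <- 99L
  d3 <- simulate_dataset(p3, out_dir = tempfile())
  expect_false(identical(readLines(d1$sam), readLines(d3$sam)))
})

test_that("depth 0 yields a valid header-only SAM", {
  p <- sim_params(genome_length = 120000L, n_mei_per_class = 0L,
                  n_med_per_class = 0L, n_ordinary_sv = 0L, depth = 0,
                  seed = 7L)
  sim <- simulate_genome(p)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(sim, p, sam)
  lines <- readLines(sam)
  expect_true(all(startsWith(lines, "@")))
  out <- scan_alignments(sam)
  expect_equal(nrow(out$spans), 0L)
})

test_that("read count concentrates near the coverage expectation", {
  p <- sim_params(genome_length = 150000L, n_mei_per_class = 0L,
                  n_med_per_class = 0L, n_ordinary_sv = 0L, depth = 30,
                  read_length_mean = 5000L, read_length_sd = 500L, seed = 8L)
  sim <- simulate_genome(p)
  sam <- tempfile(fileext = ".sam")
  rd <- simulate_reads(sim, p, sam)
  expected <- 30 * 150000 / 5000
  expect_lt(abs(rd$n_reads - expected), 3 * sqrt(expected) + 2)
})

test_that("every emitted record has a query-consistent CIGAR", {
  d <- local_small_dataset()
  lines <- grep("^[^@]", readLines(d$sam), value = TRUE)
  f <- strsplit(lines, "\t")
  for (r in f) {
    cig <- r[6]
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    opc <- substring(ops, nchar(ops), nchar(ops))
    opl <- as.integer(substring(ops, 1, nchar(ops) - 1))
    qlen <- sum(opl[opc %in% c("M", "I", "S", "=", "X")])
    expect_equal(qlen, nchar(r[10]), info = r[1])
  }
  # and samtools-style parsing via Rsamtools worked upstream in scan
  expect_gt(length(f), 100)
})

test_that("reads across a homozygous MEI carry the insertion as an I op", {
  lib <- builtin_me_library()
  p <- sim_params(genome_length = 120000L, n_mei_per_class = 0L,
                  n_med_per_class = 0L, n_ordinary_sv = 0L, depth = 20,
                  het_fraction = 0, substitution_rate = 0, indel_rate = 0,
                  seed = 9L)
  sim <- simulate_genome(p)
  # implant one Alu MEI by hand through the truth mechanism
  alu <- lib$templates$sequence[lib$templates$me_class == "Alu"]
  truth <- data.frame(chrom = "simchr1", pos = 60000L, svtype = "INS",
                      svlen = nchar(alu), me_class = "Alu", gt = "1|1",
                      seq = alu, stringsAsFactors = FALSE)
  sim$truth <- truth
  sim$hap1 <- mevcall:::.build_haplotype(sim$reference[[1]], truth, 1L)
  sim$hap2 <- mevcall:::.build_haplotype(sim$reference[[1]], truth, 2L)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(sim, p, sam)
  out <- scan_alignments(sam, cfg = caller_config(min_support = 1L))
  spanning <- out$spans$ref_start < 59000 & out$spans$ref_end > 61000
  sig <- out$signatures[out$signatures$svtype == "INS", ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$pos == 60000L))
  expect_true(all(sig$length == nchar(alu)))
  expect_true(all(sig$inserted_sequence == alu))
  # every read spanning the window contributes a signature (reads partially
  # overlapping the event may contribute one too without spanning)
  expect_true(all(out$spans$read_name[spanning] %in% sig$read_name))
})

test_that("large deletions split reads with reciprocal SA tags and the
           split channel recovers them", {
  # a long template forces the deletion above split_del_threshold
  lib <- structure(list(templates = data.frame(
    name = "L1_long_synthetic", me_class = "L1",
    sequence = mevcall:::.lcg_dna(6000, 99), length = 6000L,
    stringsAsFactors = FALSE)), class = "MELibrary")
  p <- sim_params(genome_length = 150000L, n_mei_per_class = 0L,
                  n_med_per_class = 1L, n_ordinary_sv = 0L, depth = 20,
                  het_fraction = 0, l1_truncation = FALSE,
                  split_del_threshold = 3000L,
                  substitution_rate = 0, indel_rate = 0, seed = 10L)
  lib1 <- lib
  # classes without templates must have zero counts: bypass via direct calls
  sim <- simulate_genome(sim_params(genome_length = 150000L,
                                    n_mei_per_class = 0L, n_med_per_class = 0L,
                                    n_ordinary_sv = 0L, depth = 20,
                                    het_fraction = 0, seed = 10L))
  del_seq <- lib1$templates$sequence[1]
  pos <- 70000L
  ref_seq <- paste0(substring(sim$reference[[1]], 1, pos), del_seq,
                    substring(sim$reference[[1]], pos + 1))
  truth <- data.frame(chrom = "simchr1", pos = pos, svtype = "DEL",
                      svlen = -6000L, me_class = "L1", gt = "1|1",
                      seq = del_seq, stringsAsFactors = FALSE)
  sim$reference <- c(simchr1 = ref_seq)
  sim$hap1 <- mevcall:::.build_haplotype(ref_seq, truth, 1L)
  sim$hap2 <- mevcall:::.build_haplotype(ref_seq, truth, 2L)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(sim, p, sam)
  lines <- grep("^[^@]", readLines(sam), value = TRUE)
  expect_true(any(grepl("SA:Z:", lines)))
  supp <- sum(bitwAnd(as.integer(vapply(strsplit(lines, "\t"), `[[`,
                                        character(1), 2)), 2048L) > 0)
  expect_gt(supp, 0)
  out <- scan_alignments(sam, cfg = caller_config(min_support = 1L))
  split_sigs <- out$signatures[out$signatures$source == "split", ]
  expect_gt(nrow(split_sigs), 0)
  expect_true(all(split_sigs$svtype == "DEL"))
  expect_true(all(split_sigs$pos == pos))
  expect_true(all(split_sigs$length == 6000L))
  # the full caller recovers and classifies the deletion
  ref_fa <- tempfile(fileext = ".fa")
  writeLines(c(">simchr1", ref_seq), ref_fa)
  calls <- call_mevs(sam, ref_fa, lib = lib1,
                     cfg = caller_config(min_support = 3L))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$svtype, "DEL")
  expect_equal(calls$me_class, "L1")
  expect_equal(calls$gt, "1/1")
})
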