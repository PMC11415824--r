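cfg50 <- caller_config(min_support = 1L, min_signature_size = 50L)

aln <- function(cigar, seq, ref_start = 1000L, name = "r1") {
  list(read_name = name, chrom = "simchr1", ref_start = ref_start,
       cigar = cigar, seq = seq, mapq = 60L, strand = "+", sa_tags = NULL)
}

test_that("CIGAR signature extraction places INS and DEL correctly", {
  # no indel ops
  expect_equal(nrow(extract_cigar_signatures(
    aln("100M", strrep("A", 100), 500L), cfg50)), 0L)

  # 50M 300I 50M: INS at ref 1050 carrying read bases 50..349 (0-based)
  seq <- paste0(strrep("C", 50), strrep("G", 300), strrep("T", 50))
  s <- extract_cigar_signatures(aln("50M300I50M", seq, 1000L), cfg50)
  expect_equal(nrow(s), 1L)
  expect_equal(s$svtype, "INS")
  expect_equal(s$pos, 1050L)
  expect_equal(s$length, 300L)
  expect_identical(s$inserted_sequence, strrep("G", 300))

  # below threshold
  seq2 <- paste0(strrep("C", 50), strrep("G", 20), strrep("T", 50))
  expect_equal(nrow(extract_cigar_signatures(
    aln("50M20I50M", seq2), cfg50)), 0L)

  # 40M 310D 40M: DEL at 2040
  s <- extract_cigar_signatures(aln("40M310D40M", strrep("A", 80), 2000L), cfg50)
  expect_equal(s$svtype, "DEL")
  expect_equal(s$pos, 2040L)
  expect_equal(s$length, 310L)
  expect_identical(s$inserted_sequence, "")
})

test_that("malformed CIGARs are rejected with a clear error", {
  expect_error(extract_cigar_signatures(aln("50M", strrep("A", 60)), cfg50),
               "query-consuming")
  expect_error(extract_cigar_signatures(aln("xyz", strrep("A", 60)), cfg50),
               "malformed CIGAR")
})

test_that("split-read signatures follow the q/g gap arithmetic", {
  # two segments: primary covers read[0,400) at ref 1000; SA covers
  # read[1000,1400) at ref 1400 -> q = 600, g = 0 -> INS 600 at ref 1400
  seq <- random_dna(1400)
  p <- aln("400M1000S", seq, 1000L)
  p$sa_tags <- data.frame(chrom = "simchr1", pos = 1400L, strand = "+",
                          cigar = "1000S400M", stringsAsFactors = FALSE)
  s <- extract_split_signatures(p, cfg50)
  expect_equal(nrow(s), 1L)
  expect_equal(s$svtype, "INS")
  expect_equal(s$length, 600L)
  expect_equal(s$pos, 1400L)
  expect_equal(s$source, "split")
  expect_identical(s$inserted_sequence, substring(seq, 401, 1000))

  # colinear segments, g == q: nothing
  p2 <- aln("400M400S", random_dna(800), 1000L)
  p2$sa_tags <- data.frame(chrom = "simchr1", pos = 1400L, strand = "+",
                           cigar = "400S400M", stringsAsFactors = FALSE)
  expect_equal(nrow(extract_split_signatures(p2, cfg50)), 0L)

  # opposite strands: pair skipped
  p3 <- p
  p3$sa_tags$strand <- "-"
  expect_equal(nrow(extract_split_signatures(p3, cfg50)), 0L)

  # reference gap larger than query gap: DEL
  p4 <- aln("400M400S", random_dna(800), 1000L)
  p4$sa_tags <- data.frame(chrom = "simchr1", pos = 2000L, strand = "+",
                           cigar = "400S400M", stringsAsFactors = FALSE)
  s4 <- extract_split_signatures(p4, cfg50)
  expect_equal(s4$svtype, "DEL")
  expect_equal(s4$length, 600L)
  expect_equal(s4$pos, 1400L)

  # hard clips count toward query offsets
  p5 <- aln("400M1000S", seq, 1000L)
  p5$sa_tags <- data.frame(chrom = "simchr1", pos = 1400L, strand = "+",
                           cigar = "1000H400M", stringsAsFactors = FALSE)
  expect_equal(extract_split_signatures(p5, cfg50)$length, 600L)
})

test_that("scan_alignments handles empty and filtered inputs", {
  sam <- write_test_sam(character(0))
  out <- scan_alignments(sam)
  expect_equal(nrow(out$signatures), 0L)
  expect_equal(nrow(out$spans), 0L)

  # secondary / supplementary / low-mapq records are not used directly
  recs <- c(
    sam_record("sec", 100L, "60M", strrep("A", 60), flag = 256L),
    sam_record("sup", 200L, "60M", strrep("A", 60), flag = 2048L),
    sam_record("lowq", 300L, "60M", strrep("A", 60), mapq = 5L)
  )
  out2 <- scan_alignments(write_test_sam(recs))
  expect_equal(nrow(out2$spans), 0L)
})

test_that("unsorted input is a fatal error naming the requirement", {
  sam <- write_test_sam(
    sam_record("r1", 500L, "60M", strrep("A", 60)), sorted = FALSE)
  expect_error(scan_alignments(sam), "coordinate-sorted")

  # sorted flag present but records out of order
  recs <- c(sam_record("r1", 900L, "60M", strrep("A", 60)),
            sam_record("r2", 100L, "60M", strrep("A", 60)))
  expect_error(scan_alignments(write_test_sam(recs)), "coordinate-sorted")
})

test_that("scan finds simulated homozygous insertions with full support", {
  d <- local_small_dataset()
  cfg <- caller_config(min_support = 3L)
  out <- scan_alignments(d$sam, cfg = cfg)
  expect_gt(nrow(out$signatures), 0L)
  hom_ins <- d$truth[d$truth$svtype == "INS" & d$truth$gt == "1|1" &
                       d$truth$me_class != "none", , drop = FALSE]
  skip_if(nrow(hom_ins) == 0L)
  for (i in seq_len(nrow(hom_ins))) {
    near <- out$signatures$svtype == "INS" &
      abs(out$signatures$pos - hom_ins$pos[i]) <= cfg$cluster_max_distance
    expect_gte(length(unique(out$signatures$read_name[near])), cfg$min_support)
  }
})

test_that("region restriction excludes distant loci", {
  d <- local_small_dataset()
  tr <- d$truth[d$truth$me_class != "none", , drop = FALSE]
  target <- tr$pos[1]
  # a window far away from the first event
  far <- tr$pos[which.max(abs(tr$pos - target))]
  out <- scan_alignments(d$sam, region = sprintf("simchr1:%d-%d",
                                                 target - 200L, target + 200L))
  expect_true(all(abs(out$signatures$pos - far) > 500 |
                    out$signatures$svtype != tr$svtype[which.max(abs(tr$pos - target))]))
  expect_true(any(abs(out$signatures$pos - target) < 1000))
})

test_that("signature coordinates lie within the source read's span and INS
           counts equal the qualifying I ops", {
  d <- local_small_dataset()
  out <- scan_alignments(d$sam)
  sig <- out$signatures
  sp <- out$spans
  m <- match(sig$read_name, sp$read_name)
  expect_true(all(sig$pos >= sp$ref_start[m] & sig$pos <= sp$ref_end[m]))

  # per-read INS signature count == number of I ops >= threshold (+ split)
  cfg <- caller_config()
  set.seed(3)
  for (rep in 1:10) {
    nseg <- sample(2:4, 1)
    ilens <- sample(c(10L, 40L, 200L, 500L), nseg - 1L, replace = TRUE)
    cig <- paste0("100M", paste0(ilens, "I", "100M", collapse = ""))
    qlen <- 100L * nseg + sum(ilens)
    a <- aln(cig, random_dna(qlen), 5000L)
    s <- extract_cigar_signatures(a, cfg)
    expect_equal(nrow(s), sum(ilens >= cfg$min_signature_size))
  }
})
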