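# Shared fixtures built in code at test time.

# write a minimal coordinate-sorted SAM around the given record lines
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           ref_len = 100000L, sorted = TRUE) {
  hd <- if (sorted) "@HD\tVN:1.6\tSO:coordinate" else "@HD\tVN:1.6"
  writeLines(c(hd, paste0("@SQ\tSN:simchr1\tLN:", ref_len), records), path)
  path
}

sam_record <- function(qname, pos1, cigar, seq, flag = 0L, mapq = 60L,
                       chrom = "simchr1", tags = character(0)) {
  paste(c(qname, flag, chrom, pos1, mapq, cigar, "*", 0, 0, seq, "*", tags),
        collapse = "\t")
}

# small, fast simulation design shared by several tests
small_sim_params <- function(...) {
  sim_params(genome_length = 120000L, n_mei_per_class = 2L,
             n_med_per_class = 2L, n_ordinary_sv = 4L, depth = 30,
             read_length_mean = 6000L, read_length_sd = 800L, ...)
}

# one cached small dataset reused across test files (simulate once)
local_small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(small_sim_params(seed = 7L))
    }
    cache
  }
})
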