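#' Run one simulate-call-evaluate benchmark round
#'
#' Simulates a dataset, runs the full caller, writes and re-reads the call
#' VCF (so the evaluated calls are exactly what a user would see on disk),
#' and returns the call and truth tables. Temporary files are removed.
#'
#' @param params a [sim_params()].
#' @param cfg a [caller_config()].
#' @param lib an `MELibrary`.
#' @return list with `calls` and `truth` tables (as parsed from VCF) and
#'   `n_reads`.
#' @export
run_benchmark_seed <- function(params, cfg, lib = builtin_me_library()) {
  out_dir <- tempfile("bench")
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  d <- simulate_dataset(params, lib, out_dir = out_dir)
  ref <- load_reference(d$ref)
  calls <- call_mevs(d$sam, ref, lib = lib, cfg = cfg)
  rownames(calls) <- NULL
  vcf <- file.path(out_dir, "calls.vcf")
  write_mev_vcf(calls, ref, vcf, fixed_date = TRUE)
  list(calls = read_mev_vcf(vcf), truth = read_mev_vcf(d$truth_vcf),
       n_reads = d$n_reads)
}
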