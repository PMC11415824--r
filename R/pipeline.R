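#' Call mobile element variants from long-read alignments
#'
#' The full pipeline: (1) harvest insertion/deletion signatures from CIGAR
#' strings and split-read placements; (2) cluster signatures per locus and
#' build one consensus sequence per cluster; (3) classify each consensus as
#' Alu, L1 or SVA — first by template alignment, then, for fragmented
#' leftovers passing the k-mer prescreen, by the second-round classifier;
#' (4) genotype classified calls from supporting versus reference-spanning
#' read counts. Only ME-classified, genotyped calls are returned; candidate
#' SVs that match no template (e.g. ordinary insertions of random sequence)
#' are dropped.
#'
#' @param alignments coordinate-sorted SAM or BAM path.
#' @param reference reference genome: FASTA path or a [load_reference()]
#'   accessor.
#' @param lib ME template library: an `MELibrary`, a FASTA path, or
#'   `"builtin"`.
#' @param cfg a [caller_config()]; `cfg$min_support` is the `-s` parameter.
#' @param region optional `"chrom:start-end"` restriction.
#' @param keep_unclassified also return unclassified SV candidates (as
#'   `me_class = "none"` rows); off by default, matching the tool's scope.
#' @return data frame of calls, sorted by `(chrom, pos)`, with columns
#'   `chrom`, `pos` (0-based anchor; printed 1-based by [write_mev_vcf()]),
#'   `svtype`, `svlen`, `me_class`, `gt`, `dr`, `dv`, `consensus_sequence`,
#'   `classification_round`.
#' @export
call_mevs <- function(alignments, reference, lib = "builtin",
                      cfg = caller_config(), region = NULL,
                      keep_unclassified = FALSE) {
  if (is.character(lib)) lib <- load_me_library(lib)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference))) {
    reference <- load_reference(reference)
  }
  scan <- scan_alignments(alignments, region = region, cfg = cfg)
  plugin <- cfg$second_round_plugin
  if (is.null(plugin)) plugin <- kmer_profile_classifier(lib)

  calls <- list()
  for (chrom in unique(scan$signatures$chrom)) {
    sigs <- scan$signatures[scan$signatures$chrom == chrom, , drop = FALSE]
    clusters <- cluster_signatures(sigs, cfg)
    for (cl in clusters) {
      cons <- build_consensus(cl, reference, cfg)
      if (cons$consensus_length < cfg$min_signature_size) next
      klass <- classify_consensus(cons$consensus_sequence, lib, cfg,
                                  plugin = plugin)
      if (klass$me_class == "none" && !keep_unclassified) next
      dv <- cl$support
      dr <- count_reference_spanning(cl$chrom, cl$anchor_pos, scan$spans,
                                     unique(cl$members$read_name),
                                     flank = cfg$spanning_flank)
      gt <- genotype_call(dv, dr, cfg)
      if (is.na(gt)) next
      svlen <- if (cl$svtype == "INS") cons$consensus_length else
        -cl$median_length
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = cl$chrom, pos = cl$anchor_pos, svtype = cl$svtype,
        svlen = svlen, me_class = klass$me_class, gt = gt, dr = dr, dv = dv,
        consensus_sequence = cons$consensus_sequence,
        classification_round = if (klass$me_class == "none") "none" else
          klass$round,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), pos = integer(0), svtype = character(0),
               svlen = integer(0), me_class = character(0), gt = character(0),
               dr = integer(0), dv = integer(0),
               consensus_sequence = character(0),
               classification_round = character(0), stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Run the caller and write a VCF
#'
#' Convenience wrapper: [call_mevs()] followed by [write_mev_vcf()].
#'
#' @inheritParams call_mevs
#' @param out_path output VCF path.
#' @param sample sample column name.
#' @param ... passed to [write_mev_vcf()] (e.g. `fixed_date`,
#'   `explicit_del_alleles`).
#' @return the call table, invisibly.
#' @export
call_mevs_vcf <- function(alignments, reference, out_path, lib = "builtin",
                          cfg = caller_config(), region = NULL,
                          sample = "SAMPLE", ...) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference))) {
    reference <- load_reference(reference)
  }
  calls <- call_mevs(alignments, reference, lib = lib, cfg = cfg,
                     region = region)
  rownames(calls) <- NULL
  write_mev_vcf(calls, reference, out_path, sample = sample, ...)
  invisible(calls)
}
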