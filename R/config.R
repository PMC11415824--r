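#' Caller configuration
#'
#' All tunable parameters of the calling pipeline in one validated object.
#' `min_support` is the `-s` parameter of the command line interface: the
#' minimum number of distinct reads that must carry a signature for a
#' candidate locus to survive clustering.
#'
#' @param min_support minimum distinct supporting reads per call (`-s`).
#' @param min_signature_size smallest insertion/deletion signature (bp)
#'   harvested from an alignment. Default 30 bp: well below the ~300 bp Alu
#'   scale so fragmented signatures still contribute.
#' @param min_mapq minimum mapping quality of a primary alignment.
#' @param cluster_max_distance maximum reference-position gap (bp) between
#'   adjacent signatures chained into one cluster.
#' @param cluster_size_ratio minimum `min(len)/max(len)` ratio between a
#'   joining signature and the cluster's running median length, in (0, 1].
#' @param het_af_low,hom_af_high allele-frequency bands for genotyping:
#'   `af < het_af_low` is filtered (no call), `af` in `[het_af_low,
#'   hom_af_high]` is `0/1`, above is `1/1`.
#' @param sw_match,sw_mismatch,sw_gap_open,sw_gap_extend local alignment
#'   scoring; a gap of length L costs `sw_gap_open + L * sw_gap_extend`.
#' @param first_round_identity_threshold minimum alignment identity
#'   (matches / aligned query columns) for a first-round class assignment.
#' @param first_round_span_fraction minimum fraction of the template length
#'   the alignment's query span must cover for a first-round assignment;
#'   shorter (fragmented) matches are deferred to the second round.
#' @param prescreen_k k-mer size of the second-round prescreen.
#' @param prescreen_min_fraction minimum fraction of the consensus's distinct
#'   k-mers shared with some template (either strand) to pass the prescreen.
#' @param second_round_enabled logical; `FALSE` reproduces the ablation mode
#'   in which fragmented events rely on the first round only.
#' @param second_round_plugin a second-round classifier created by
#'   [kmer_profile_classifier()] or any function implementing the plugin
#'   contract (see [classify_second_round()]); `NULL` uses the default
#'   k-mer-profile baseline.
#' @param spanning_flank half-width (bp) of the window a read must span,
#'   around the call position, to be counted as reference-supporting (`DR`).
#' @param max_consensus_reads cap on the number of member sequences fed to
#'   the consensus step (longest-first subsample by median-length proximity).
#' @param seed integer seed for any stochastic step in the caller (none by
#'   default; kept for forward compatibility).
#' @return An object of class `CallerConfig` (a validated named list).
#' @export
caller_config <- function(min_support = 3L,
                          min_signature_size = 30L,
                          min_mapq = 20L,
                          cluster_max_distance = 1000L,
                          cluster_size_ratio = 0.7,
                          het_af_low = 0.2,
                          hom_af_high = 0.8,
                          sw_match = 2L,
                          sw_mismatch = -4L,
                          sw_gap_open = -4L,
                          sw_gap_extend = -2L,
                          first_round_identity_threshold = 0.7,
                          first_round_span_fraction = 0.5,
                          prescreen_k = 11L,
                          prescreen_min_fraction = 0.2,
                          second_round_enabled = TRUE,
                          second_round_plugin = NULL,
                          spanning_flank = 500L,
                          max_consensus_reads = 10L,
                          seed = 1L) {
  cfg <- list(
    min_support = as.integer(min_support),
    min_signature_size = as.integer(min_signature_size),
    min_mapq = as.integer(min_mapq),
    cluster_max_distance = as.integer(cluster_max_distance),
    cluster_size_ratio = cluster_size_ratio,
    het_af_low = het_af_low,
    hom_af_high = hom_af_high,
    sw_match = as.integer(sw_match),
    sw_mismatch = as.integer(sw_mismatch),
    sw_gap_open = as.integer(sw_gap_open),
    sw_gap_extend = as.integer(sw_gap_extend),
    first_round_identity_threshold = first_round_identity_threshold,
    first_round_span_fraction = first_round_span_fraction,
    prescreen_k = as.integer(prescreen_k),
    prescreen_min_fraction = prescreen_min_fraction,
    second_round_enabled = isTRUE(second_round_enabled),
    second_round_plugin = second_round_plugin,
    spanning_flank = as.integer(spanning_flank),
    max_consensus_reads = as.integer(max_consensus_reads),
    seed = as.integer(seed)
  )
  if (cfg$min_support < 1L) stop("min_support must be >= 1")
  if (cfg$min_signature_size < 1L) stop("min_signature_size must be >= 1")
  if (!(cfg$het_af_low > 0 && cfg$het_af_low < cfg$hom_af_high &&
        cfg$hom_af_high < 1)) {
    stop("need 0 < het_af_low < hom_af_high < 1")
  }
  if (cfg$cluster_size_ratio <= 0 || cfg$cluster_size_ratio > 1) {
    stop("cluster_size_ratio must be in (0, 1]")
  }
  if (cfg$prescreen_k < 4L) stop("prescreen_k must be >= 4")
  if (cfg$sw_match <= 0L) stop("sw_match must be positive")
  if (cfg$sw_mismatch >= 0L || cfg$sw_gap_open > 0L || cfg$sw_gap_extend > 0L) {
    stop("sw_mismatch must be negative; gap penalties must be non-positive")
  }
  class(cfg) <- "CallerConfig"
  cfg
}

#' @export
print.CallerConfig <- function(x, ...) {
  cat("CallerConfig:\n")
  flat <- x[!vapply(x, is.function, logical(1))]
  flat$second_round_plugin <- NULL
  str(unclass(flat), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
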