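#' @useDynLib mevcall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Distinct k-mers of a sequence (character vector). Sequences shorter than k
# yield character(0).
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Anchor diagonal for the band: the diagonal (tpos - qpos) voted for by the
# most shared k-mers, mapping each query k-mer to its first occurrence in
# the target (keeps low-complexity runs such as polyA tails from flooding
# the vote). Returns NA when no k-mer is shared.
.anchor_diagonal <- function(query, target, k) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq < k || nt < k) return(NA_integer_)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  tk <- substring(target, 1:(nt - k + 1L), k:nt)
  first_t <- match(qk, tk)           # first target occurrence per query k-mer
  hit <- which(!is.na(first_t))
  if (length(hit) == 0L) return(NA_integer_)
  diag <- first_t[hit] - hit
  tab <- table(diag)
  as.integer(names(tab)[which.max(tab)])
}

.sw_one_strand <- function(query, target, cfg, band) {
  n <- nchar(query); m <- nchar(target)
  band_diag <- 0L; band_width <- -1L
  if (band && max(n, m) > 256L) {
    d0 <- .anchor_diagonal(query, target, cfg$prescreen_k)
    if (!is.na(d0)) {
      band_diag <- d0
      band_width <- as.integer(max(64L, ceiling(0.2 * max(n, m))))
    }
  }
  .sw_align_cpp(query, target, cfg$sw_match, cfg$sw_mismatch,
                cfg$sw_gap_open, cfg$sw_gap_extend, band_diag, band_width)
}

#' Local alignment of a consensus sequence against an ME template
#'
#' Affine-gap Smith-Waterman, run on both strands of the query (as given and
#' reverse-complemented); the orientation with the higher score wins, with a
#' tie broken towards `+`. For sequences longer than 256 bp the dynamic
#' program is restricted to a diagonal band of half-width
#' `max(64, 0.2 * max(n, m))` centred on the diagonal that shares the most
#' k-mers with the target (unbanded when no k-mer is shared, and always
#' unbanded at small sizes, where the band would change nothing). `N` scores
#' 0 against everything and never counts as a match.
#'
#' @param query,target non-empty DNA strings (`ACGTN`).
#' @param cfg a [caller_config()] supplying the scoring parameters.
#' @param band logical; set `FALSE` to force the full unbanded dynamic
#'   program.
#' @return list with `score`, `identity` (matches / query-consuming aligned
#'   columns), `query_span` and `target_span` (0-based half-open, on the
#'   original query orientation), and `strand` (`"+"` or `"-"`).
#' @export
smith_waterman <- function(query, target, cfg = caller_config(), band = TRUE) {
  stopifnot(is.character(query), is.character(target))
  if (nchar(query) == 0L || nchar(target) == 0L) {
    stop("smith_waterman(): empty sequence")
  }
  query <- toupper(query); target <- toupper(target)
  fwd <- .sw_one_strand(query, target, cfg, band)
  rcq <- revcomp(query)
  rev <- .sw_one_strand(rcq, target, cfg, band)
  n <- nchar(query)
  if (rev$score > fwd$score) {
    res <- rev
    strand <- "-"
    qspan <- c(n - res$qend, n - res$qstart)  # map back to original orientation
  } else {
    res <- fwd
    strand <- "+"
    qspan <- c(res$qstart, res$qend)
  }
  identity <- if (res$query_cols > 0) res$matches / res$query_cols else 0
  list(score = res$score,
       identity = identity,
       query_span = qspan,
       target_span = c(res$tstart, res$tend),
       strand = strand,
       matches = res$matches,
       aligned_query_cols = res$query_cols)
}

.unclassified <- function() {
  list(me_class = "none", best_template = NULL, sw = NULL,
       round = "unclassified", second_round_score = NULL)
}

#' First-round classification by template alignment
#'
#' The consensus sequence is aligned (both strands) against every template in
#' the library. The best-scoring template's class is assigned iff the
#' alignment identity reaches `first_round_identity_threshold` and the query
#' span covers at least `first_round_span_fraction` of the template length;
#' fragmented matches below that coverage are deliberately left unclassified
#' so the second round can examine them. Ties on score are broken by higher
#' identity, then shorter template, then template name.
#'
#' @param consensus_sequence DNA string (a `ConsensusCall`'s sequence).
#' @param lib an `MELibrary`.
#' @param cfg a [caller_config()].
#' @return An `MEClassification` list: `me_class` (`Alu`/`L1`/`SVA`/`none`),
#'   `best_template`, `sw` (the winning alignment), `round`
#'   (`first`/`unclassified`), `second_round_score` (`NULL` here).
#' @export
classify_first_round <- function(consensus_sequence, lib, cfg = caller_config()) {
  stopifnot(inherits(lib, "MELibrary"))
  if (nrow(lib$templates) == 0L) stop("empty ME library")
  tmpl <- lib$templates
  results <- lapply(seq_len(nrow(tmpl)), function(i) {
    smith_waterman(consensus_sequence, tmpl$sequence[i], cfg)
  })
  score <- vapply(results, `[[`, numeric(1), "score")
  ident <- vapply(results, `[[`, numeric(1), "identity")
  ord <- order(-score, -ident, tmpl$length, tmpl$name)
  best <- ord[1]
  sw <- results[[best]]
  qspan <- sw$query_span[2] - sw$query_span[1]
  ok <- sw$score > 0 &&
    sw$identity >= cfg$first_round_identity_threshold &&
    qspan >= cfg$first_round_span_fraction * tmpl$length[best]
  if (!ok) return(.unclassified())
  list(me_class = tmpl$me_class[best], best_template = tmpl$name[best],
       sw = sw, round = "first", second_round_score = NULL)
}

#' k-mer prescreen for the second round
#'
#' Cheap filter excluding sequences unrelated to every template: passes iff,
#' for some template (on either strand of the consensus), the fraction of the
#' consensus's distinct k-mers shared with the template is at least
#' `prescreen_min_fraction`.
#'
#' @param consensus_sequence DNA string; shorter than `prescreen_k` returns
#'   `FALSE`.
#' @param lib an `MELibrary`.
#' @param cfg a [caller_config()].
#' @return logical scalar.
#' @export
kmer_prescreen <- function(consensus_sequence, lib, cfg = caller_config()) {
  k <- cfg$prescreen_k
  qk <- .kmers(toupper(consensus_sequence), k)
  if (length(qk) == 0L) return(FALSE)
  qk_rc <- .kmers(revcomp(consensus_sequence), k)
  for (i in seq_len(nrow(lib$templates))) {
    tk <- .kmers(lib$templates$sequence[i], k)
    frac_f <- mean(qk %in% tk)
    frac_r <- mean(qk_rc %in% tk)
    if (max(frac_f, frac_r) >= cfg$prescreen_min_fraction) return(TRUE)
  }
  FALSE
}

#' Baseline second-round classifier: per-class k-mer containment
#'
#' Builds the distinct k-mer sets (default k = 6) of every template and
#' classifies a sequence by the class whose templates contain the largest
#' fraction of the sequence's distinct k-mers (max over templates and
#' strands). The containment fraction itself is the confidence. Containment
#' rather than a symmetric similarity is deliberate: second-round inputs are
#' typically fragments, and a 40% fragment of a template still has near-total
#' k-mer containment in it while any symmetric measure is depressed by the
#' missing part.
#'
#' This is the default plug-in filling the second-round slot; a heavier
#' model (e.g. a fine-tuned language model over DNA) can replace it by
#' supplying any function with the same contract to
#' `caller_config(second_round_plugin = )`.
#'
#' @param lib an `MELibrary` the profiles are built from.
#' @param k k-mer size of the profiles.
#' @param threshold minimum confidence for a class assignment.
#' @return A function `(sequence) -> list(me_class, confidence)` implementing
#'   the second-round plugin contract.
#' @export
kmer_profile_classifier <- function(lib, k = 6L, threshold = 0.5) {
  stopifnot(inherits(lib, "MELibrary"))
  profiles <- lapply(seq_len(nrow(lib$templates)), function(i) {
    .kmers(lib$templates$sequence[i], k)
  })
  classes <- lib$templates$me_class
  function(sequence) {
    qk <- .kmers(toupper(sequence), k)
    if (length(qk) == 0L) return(list(me_class = "none", confidence = 0))
    qk_rc <- .kmers(revcomp(sequence), k)
    conf <- vapply(profiles, function(tk) {
      max(mean(qk %in% tk), mean(qk_rc %in% tk))
    }, numeric(1))
    best <- which.max(conf)
    if (conf[best] < threshold) return(list(me_class = "none",
                                            confidence = conf[best]))
    list(me_class = classes[best], confidence = conf[best])
  }
}

#' Second-round classification of first-round leftovers
#'
#' Applied only to sequences the first round left unclassified and that pass
#' the k-mer prescreen. Delegates to the plugin: a function receiving the
#' consensus sequence and returning `list(me_class, confidence)`; the class
#' is assigned iff `me_class != "none"`. A plugin error is caught, logged as
#' a warning, and leaves the call unclassified — the pipeline never crashes
#' on a plugin.
#'
#' @param consensus_sequence DNA string.
#' @param lib an `MELibrary`.
#' @param plugin a plugin function, e.g. from [kmer_profile_classifier()].
#' @param cfg a [caller_config()].
#' @return An `MEClassification` list with `round = "second"` on success.
#' @export
classify_second_round <- function(consensus_sequence, lib, plugin,
                                  cfg = caller_config()) {
  out <- tryCatch(plugin(consensus_sequence), error = function(e) {
    warning("second-round plugin failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(out) || !is.list(out) || is.null(out$me_class) ||
      !out$me_class %in% c(ME_CLASSES, "none") || identical(out$me_class, "none")) {
    res <- .unclassified()
    res$second_round_score <- if (is.list(out)) out$confidence else NULL
    return(res)
  }
  list(me_class = out$me_class, best_template = NULL, sw = NULL,
       round = "second", second_round_score = out$confidence)
}

#' Full two-round classification of one consensus sequence
#'
#' @param consensus_sequence DNA string.
#' @param lib an `MELibrary`.
#' @param cfg a [caller_config()]; `cfg$second_round_enabled = FALSE` is the
#'   ablation mode in which only the alignment round runs.
#' @param plugin optional second-round plugin; defaults to
#'   `cfg$second_round_plugin`, or the [kmer_profile_classifier()] baseline.
#' @return An `MEClassification` list.
#' @export
classify_consensus <- function(consensus_sequence, lib, cfg = caller_config(),
                               plugin = NULL) {
  first <- classify_first_round(consensus_sequence, lib, cfg)
  if (first$me_class != "none") return(first)
  if (!cfg$second_round_enabled) return(first)
  if (!kmer_prescreen(consensus_sequence, lib, cfg)) return(first)
  if (is.null(plugin)) plugin <- cfg$second_round_plugin
  if (is.null(plugin)) plugin <- kmer_profile_classifier(lib)
  classify_second_round(consensus_sequence, lib, plugin, cfg)
}
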