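#' Group signatures into per-locus clusters
#'
#' Signatures of each SV type are sorted by position (ties broken by length,
#' read name and source so shuffled input yields identical clusters) and
#' chained by single linkage: a signature joins the open cluster iff its
#' position gap to the previously chained member is at most
#' `cluster_max_distance` and its length agrees with the cluster's running
#' median length to within `cluster_size_ratio` (min/max ratio). Clusters
#' supported by fewer than `min_support` distinct reads are discarded.
#'
#' @param signatures data frame as produced by [scan_alignments()]; all on
#'   one chromosome.
#' @param cfg a [caller_config()].
#' @return list of clusters; each is a list with `chrom`, `svtype`,
#'   `members` (data frame of signatures), `anchor_pos` (median member
#'   position), `median_length`, `support` (distinct read names).
#' @export
cluster_signatures <- function(signatures, cfg = caller_config()) {
  if (nrow(signatures) == 0L) return(list())
  if (length(unique(signatures$chrom)) > 1L) {
    stop("cluster_signatures() expects signatures from a single chromosome")
  }
  clusters <- list()
  for (svt in c("INS", "DEL")) {
    s <- signatures[signatures$svtype == svt, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$pos, s$length, s$read_name, s$source), , drop = FALSE]
    open <- integer(0)   # row indices of the open cluster
    lens <- integer(0)
    flush <- function(rows) {
      members <- s[rows, , drop = FALSE]
      support <- length(unique(members$read_name))
      if (support < cfg$min_support) return(NULL)
      list(chrom = members$chrom[1], svtype = svt, members = members,
           anchor_pos = as.integer(stats::median(members$pos)),
           median_length = as.integer(round(stats::median(members$length))),
           support = support)
    }
    for (i in seq_len(nrow(s))) {
      if (length(open) == 0L) {
        open <- i; lens <- s$length[i]
        next
      }
      gap_ok <- (s$pos[i] - s$pos[open[length(open)]]) <= cfg$cluster_max_distance
      med <- stats::median(lens)
      ratio <- min(s$length[i], med) / max(s$length[i], med)
      if (gap_ok && ratio >= cfg$cluster_size_ratio) {
        open <- c(open, i); lens <- c(lens, s$length[i])
      } else {
        cl <- flush(open)
        if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
        open <- i; lens <- s$length[i]
      }
    }
    cl <- flush(open)
    if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
  }
  ord <- order(vapply(clusters, `[[`, integer(1), "anchor_pos"),
               vapply(clusters, `[[`, character(1), "svtype"))
  clusters[ord]
}

# substring of a reference; ref is a named character vector chrom -> sequence
.ref_substring <- function(reference, chrom, start0, end0) {
  if (!chrom %in% names(reference)) stop("unknown chromosome: ", chrom)
  seq <- reference[[chrom]]
  if (start0 < 0L || end0 > nchar(seq)) {
    stop("interval [", start0, ", ", end0, ") outside reference ", chrom,
         " (length ", nchar(seq), ")")
  }
  substring(seq, start0 + 1L, end0)
}

#' Load a reference FASTA as a genome accessor
#'
#' @param fasta_path path to a (possibly multi-record) FASTA.
#' @return named character vector, chromosome name -> uppercase sequence.
#' @export
load_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# Majority-column consensus over sequences aligned to a backbone.
# Tie-break: bases in alphabetical order A < C < G < T < N; a base always
# beats a gap on ties. Columns whose strict majority is a gap are dropped.
.msa_majority_consensus <- function(seqs, cfg) {
  if (length(seqs) == 1L) return(seqs[[1]])
  if (length(unique(seqs)) == 1L) return(seqs[[1]])
  lens <- nchar(seqs)
  backbone_i <- which.min(abs(lens - stats::median(lens)))
  backbone <- seqs[backbone_i]
  others <- seqs[-backbone_i]

  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = cfg$sw_match, mismatch = cfg$sw_mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(others),
    subject = Biostrings::DNAString(backbone),
    type = "global",
    substitutionMatrix = mat,
    gapOpening = -cfg$sw_gap_open, gapExtension = -cfg$sw_gap_extend)

  nb <- nchar(backbone)
  # aligned() projects each member into backbone coordinates (insertions
  # relative to the backbone dropped, deletions as "-"); consensusMatrix
  # then gives per-column letter counts at C speed.
  a <- Biostrings::aligned(al)
  cm <- Biostrings::consensusMatrix(a)
  letters_order <- c("A", "C", "G", "T", "N", "-")  # order is the tie-break
  votes <- matrix(0L, nrow = length(letters_order), ncol = nb,
                  dimnames = list(letters_order, NULL))
  present <- intersect(letters_order, rownames(cm))
  votes[present, ] <- cm[present, , drop = FALSE]
  bb_chars <- strsplit(backbone, "")[[1]]
  bb_idx <- cbind(match(bb_chars, letters_order), seq_len(nb))
  votes[bb_idx] <- votes[bb_idx] + 1L
  win <- max.col(t(votes), ties.method = "first")  # first max = tie-break
  cons <- letters_order[win]
  paste(cons[cons != "-"], collapse = "")
}

#' Build the consensus sequence of one cluster
#'
#' INS clusters: a majority-column consensus of the members' inserted
#' sequences (a partial-order-alignment stand-in: members are globally
#' aligned to a backbone member of median length and each backbone column is
#' voted on; see the methods vignette). Unanimous members and single-member
#' clusters return the member sequence verbatim. At most
#' `cfg$max_consensus_reads` members closest to the median length are used.
#' DEL clusters: the reference substring
#' `[anchor_pos, anchor_pos + median_length)` — the content of the deleted
#' allele, which is what gets classified against the ME library.
#'
#' @param cluster one cluster from [cluster_signatures()].
#' @param reference genome accessor from [load_reference()] (named character
#'   vector); only needed for DEL clusters.
#' @param cfg a [caller_config()].
#' @return list with `cluster`, `consensus_sequence`, `consensus_length`.
#' @export
build_consensus <- function(cluster, reference = NULL, cfg = caller_config()) {
  if (is.null(cluster$members) || nrow(cluster$members) == 0L) {
    stop("empty cluster")
  }
  if (cluster$svtype == "INS") {
    seqs <- cluster$members$inserted_sequence
    if (length(seqs) > cfg$max_consensus_reads) {
      d <- abs(nchar(seqs) - stats::median(nchar(seqs)))
      seqs <- seqs[order(d)][seq_len(cfg$max_consensus_reads)]
    }
    cons <- .msa_majority_consensus(seqs, cfg)
  } else {
    if (is.null(reference)) stop("DEL consensus requires the reference")
    cons <- tryCatch(
      .ref_substring(reference, cluster$chrom, cluster$anchor_pos,
                     cluster$anchor_pos + cluster$median_length),
      error = function(e) {
        stop("cluster ", cluster$chrom, ":", cluster$anchor_pos, " (DEL, ",
             cluster$median_length, " bp): ", conditionMessage(e))
      })
  }
  list(cluster = cluster, consensus_sequence = cons,
       consensus_length = nchar(cons))
}
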