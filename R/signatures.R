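#' @title SV signature extraction from long-read alignments
#' @description Harvests insertion/deletion signatures from CIGAR strings and
#'   split-read (SA tag) placements of primary alignments, the raw material
#'   later clustered into candidate mobile element variants. Coordinates are
#'   0-based half-open throughout and converted to 1-based only when VCF is
#'   written.
#' @name signature_extraction
#' @keywords internal
NULL

QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS <- c("M", "=", "X", "D", "N")

# "100M2I30M" -> list(op = c("M","I","M"), len = c(100L, 2L, 30L))
.parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || paste(toks, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar)
  }
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

.empty_signatures <- function() {
  data.frame(chrom = character(0), pos = integer(0), svtype = character(0),
             length = integer(0), inserted_sequence = character(0),
             read_name = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Extract insertion/deletion signatures from one alignment's CIGAR
#'
#' One INS signature per `I` operation of at least `min_signature_size`,
#' placed at the reference coordinate preceding the insertion point and
#' carrying the inserted bases; one DEL signature per `D` operation of at
#' least that size, placed at the deleted interval's start.
#'
#' @param aln a list describing one primary alignment: `read_name`, `chrom`,
#'   `ref_start` (0-based), `cigar` (string), `seq` (read sequence as stored,
#'   may be `NA`), `mapq`.
#' @param cfg a [caller_config()].
#' @return data frame of signatures (possibly 0 rows) with columns `chrom`,
#'   `pos`, `svtype`, `length`, `inserted_sequence`, `read_name`, `source`.
#' @export
extract_cigar_signatures <- function(aln, cfg = caller_config()) {
  ops <- .parse_cigar(aln$cigar)
  op <- ops$op; len <- ops$len
  has_seq <- !is.null(aln$seq) && !is.na(aln$seq) && nchar(aln$seq) > 0L
  if (has_seq) {
    qlen <- sum(len[op %in% QUERY_OPS])
    if (qlen != nchar(aln$seq)) {
      stop("malformed CIGAR for read ", aln$read_name,
           ": query-consuming length ", qlen, " != sequence length ",
           nchar(aln$seq))
    }
  }
  ref_adv <- ifelse(op %in% REF_OPS, len, 0L)
  qry_adv <- ifelse(op %in% QUERY_OPS, len, 0L)
  ref_at <- aln$ref_start + cumsum(c(0L, ref_adv))[seq_along(op)]
  qry_at <- cumsum(c(0L, qry_adv))[seq_along(op)]

  ins <- which(op == "I" & len >= cfg$min_signature_size)
  del <- which(op == "D" & len >= cfg$min_signature_size)
  if (length(ins) + length(del) == 0L) return(.empty_signatures())

  ins_seq <- if (length(ins)) {
    if (has_seq) substring(aln$seq, qry_at[ins] + 1L, qry_at[ins] + len[ins])
    else strrep("N", len[ins])
  } else character(0)

  data.frame(
    chrom = aln$chrom,
    pos = c(ref_at[ins], ref_at[del]),
    svtype = c(rep("INS", length(ins)), rep("DEL", length(del))),
    length = c(len[ins], len[del]),
    inserted_sequence = c(ins_seq, rep("", length(del))),
    read_name = aln$read_name,
    source = "cigar",
    stringsAsFactors = FALSE
  )
}

# Query start/end (stored orientation, hard clips counted) and reference
# start/end of one placement.
.segment_coords <- function(ref_start, cigar) {
  ops <- .parse_cigar(cigar)
  op <- ops$op; len <- ops$len
  lead <- 0L
  i <- 1L
  while (i <= length(op) && op[i] %in% c("S", "H")) {
    lead <- lead + len[i]; i <- i + 1L
  }
  qcons <- sum(len[op %in% c("M", "=", "X", "I")])
  rcons <- sum(len[op %in% REF_OPS])
  list(qstart = lead, qend = lead + qcons,
       ref_start = ref_start, ref_end = ref_start + rcons)
}

#' Extract signatures from a split-read placement pattern
#'
#' A read whose alignment is split into a primary and one or more
#' supplementary placements (SA tag) reveals large variants through the gaps
#' between adjacent segments. For each adjacent pair, ordered by query
#' offset: with query gap `q` and reference gap `g`, `q - g >=
#' min_signature_size` yields an INS at the previous segment's reference end
#' and `g - q >= min_signature_size` a DEL there. Pairs placed on different
#' chromosomes or strands are skipped (translocation/inversion signals are
#' out of scope). All placements share the stored orientation when strands
#' agree, so query offsets from leading clips (hard clips counted) are
#' directly comparable.
#'
#' @param primary alignment list as in [extract_cigar_signatures()], plus
#'   `strand` (`"+"`/`"-"`) and `sa_tags`: a data frame of supplementary
#'   placements with columns `chrom`, `pos` (0-based), `strand`, `cigar`.
#' @param cfg a [caller_config()].
#' @return data frame of signatures with `source == "split"`.
#' @export
extract_split_signatures <- function(primary, cfg = caller_config()) {
  sa <- primary$sa_tags
  if (is.null(sa) || nrow(sa) == 0L) return(.empty_signatures())
  keep <- sa$chrom == primary$chrom & sa$strand == primary$strand
  sa <- sa[keep, , drop = FALSE]
  if (nrow(sa) == 0L) return(.empty_signatures())

  segs <- c(
    list(.segment_coords(primary$ref_start, primary$cigar)),
    lapply(seq_len(nrow(sa)), function(i) .segment_coords(sa$pos[i], sa$cigar[i]))
  )
  qs <- vapply(segs, `[[`, numeric(1), "qstart")
  ord <- order(qs)
  segs <- segs[ord]

  has_seq <- !is.null(primary$seq) && !is.na(primary$seq) && nchar(primary$seq) > 0L
  out <- list()
  for (i in seq_len(length(segs) - 1L)) {
    prev <- segs[[i]]; nxt <- segs[[i + 1L]]
    q <- nxt$qstart - prev$qend
    g <- nxt$ref_start - prev$ref_end
    if (q - g >= cfg$min_signature_size) {
      len <- q - g
      seq <- if (has_seq) substring(primary$seq, prev$qend + 1L, prev$qend + len)
             else strrep("N", len)
      out[[length(out) + 1L]] <- data.frame(
        chrom = primary$chrom, pos = prev$ref_end, svtype = "INS",
        length = len, inserted_sequence = seq,
        read_name = primary$read_name, source = "split",
        stringsAsFactors = FALSE)
    } else if (g - q >= cfg$min_signature_size) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = primary$chrom, pos = prev$ref_end, svtype = "DEL",
        length = g - q, inserted_sequence = "",
        read_name = primary$read_name, source = "split",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.empty_signatures())
  do.call(rbind, out)
}

.parse_sa_tag <- function(sa_string) {
  if (is.null(sa_string) || is.na(sa_string) || !nzchar(sa_string)) return(NULL)
  parts <- strsplit(strsplit(sa_string, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  parts <- parts[lengths(parts) >= 4L]
  if (length(parts) == 0L) return(NULL)
  data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)) - 1L,  # SA pos is 1-based
    strand = vapply(parts, `[[`, character(1), 3L),
    cigar = vapply(parts, `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

.FLAG_UNMAPPED <- 4L
.FLAG_REVERSE <- 16L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

.has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# SAM input is converted to BAM in tempdir; BAM is used as-is. Because the
# conversion sorts as a side effect, sortedness of SAM input is verified on
# the text first (the caller's contract requires coordinate-sorted input).
.check_sam_sorted <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  prev_chr <- ""; prev_pos <- -1L
  so_seen <- FALSE
  repeat {
    lines <- readLines(con, n = 5000L)
    if (length(lines) == 0L) break
    for (ln in lines) {
      if (startsWith(ln, "@")) {
        if (startsWith(ln, "@HD") && grepl("\tSO:coordinate", ln, fixed = TRUE))
          so_seen <- TRUE
        next
      }
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      pos <- as.integer(f[4])
      if (f[3] == prev_chr && pos < prev_pos) {
        stop("input alignments must be coordinate-sorted; record out of ",
             "order at ", f[3], ":", pos)
      }
      prev_chr <- f[3]; prev_pos <- pos
    }
  }
  if (!so_seen) {
    stop("input alignments must be coordinate-sorted ",
         "(header @HD line must declare SO:coordinate): ", path)
  }
  invisible(TRUE)
}

.as_bam <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    .check_sam_sorted(path)
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else {
    path
  }
}

#' Scan alignments and collect all SV signatures
#'
#' Reads a coordinate-sorted SAM or BAM, applies the mapping-quality and flag
#' filters (secondary and supplementary records are never used directly;
#' supplementary placements enter only through SA tags of primaries), and
#' concatenates CIGAR and split-read signatures from every passing read. The
#' spanned reference interval of each passing primary is recorded for
#' genotyping.
#'
#' @param path SAM or BAM file, coordinate-sorted. An index is required only
#'   when `region` is given (SAM input is converted and indexed on the fly).
#' @param region optional `"chrom:start-end"` restriction (1-based,
#'   inclusive).
#' @param cfg a [caller_config()].
#' @return list with `signatures` (data frame), `spans` (data frame
#'   `read_name`, `chrom`, `ref_start`, `ref_end` of passing primaries) and
#'   `skipped` (count of reads dropped for malformed CIGARs).
#' @export
scan_alignments <- function(path, region = NULL, cfg = caller_config()) {
  bam <- .as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  so <- hdr$text[["@HD"]]
  if (is.null(so) || !any(grepl("^SO:coordinate$", so))) {
    stop("input alignments must be coordinate-sorted ",
         "(header @HD line must declare SO:coordinate): ", path)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must look like 'chrom:start-end'")
    gr <- GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]),
                                                        as.integer(m[4])))
    param <- Rsamtools::ScanBamParam(what = what, tag = "SA", which = gr)
  } else {
    param <- Rsamtools::ScanBamParam(what = what, tag = "SA")
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]

  flag <- res$flag
  keep <- !.has_flag(flag, .FLAG_UNMAPPED) &
    !.has_flag(flag, .FLAG_SECONDARY) &
    !.has_flag(flag, .FLAG_SUPPLEMENTARY) &
    res$mapq >= cfg$min_mapq
  idx <- which(keep)

  sigs <- vector("list", length(idx))
  skipped <- 0L
  seqs <- as.character(res$seq)
  sa_raw <- res$tag$SA
  chroms <- as.character(res$rname)
  span_name <- character(length(idx)); span_chr <- character(length(idx))
  span_s <- integer(length(idx)); span_e <- integer(length(idx))
  n_span <- 0L
  prev_pos <- -1L; prev_chr <- ""
  for (k in seq_along(idx)) {
    i <- idx[k]
    chrom <- chroms[i]
    pos0 <- res$pos[i] - 1L
    if (chrom == prev_chr && pos0 < prev_pos) {
      stop("input alignments are not coordinate-sorted at ",
           chrom, ":", pos0 + 1L)
    }
    prev_chr <- chrom; prev_pos <- pos0
    aln <- list(
      read_name = res$qname[i], chrom = chrom, ref_start = pos0,
      cigar = res$cigar[i], seq = seqs[i], mapq = res$mapq[i],
      strand = if (.has_flag(flag[i], .FLAG_REVERSE)) "-" else "+",
      sa_tags = .parse_sa_tag(if (is.null(sa_raw)) NULL else sa_raw[i])
    )
    sig <- tryCatch(extract_cigar_signatures(aln, cfg), error = function(e) {
      warning("skipping read ", aln$read_name, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(sig)) {
      skipped <- skipped + 1L
      next
    }
    split_sig <- extract_split_signatures(aln, cfg)
    if (nrow(split_sig)) sig <- rbind(sig, split_sig)
    if (nrow(sig)) sigs[[k]] <- sig
    co <- .segment_coords(pos0, aln$cigar)
    n_span <- n_span + 1L
    span_name[n_span] <- aln$read_name; span_chr[n_span] <- chrom
    span_s[n_span] <- co$ref_start; span_e[n_span] <- co$ref_end
  }
  sigs <- sigs[!vapply(sigs, is.null, logical(1))]
  list(
    signatures = if (length(sigs)) do.call(rbind, sigs) else .empty_signatures(),
    spans = data.frame(read_name = span_name[seq_len(n_span)],
                       chrom = span_chr[seq_len(n_span)],
                       ref_start = span_s[seq_len(n_span)],
                       ref_end = span_e[seq_len(n_span)],
                       stringsAsFactors = FALSE),
    skipped = skipped
  )
}
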