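#' Genotype a call from read counts
#'
#' Allele-frequency bands in the style of long-read SV callers: with
#' `af = dv / (dv + dr)`, `af < het_af_low` is a no-call (the locus is
#' dropped, never emitted as 0/0), the band `[het_af_low, hom_af_high]` is
#' heterozygous `0/1`, and above it homozygous `1/1`.
#'
#' @param dv variant-supporting read count (>= 0).
#' @param dr reference-spanning read count (>= 0); `dv + dr` must be > 0.
#' @param cfg a [caller_config()].
#' @return `"0/1"`, `"1/1"`, or `NA_character_` for a no-call.
#' @export
genotype_call <- function(dv, dr, cfg = caller_config()) {
  if (dv < 0L || dr < 0L) stop("negative read counts")
  if (dv + dr == 0L) stop("genotype_call(): dv + dr must be positive")
  af <- dv / (dv + dr)
  if (af < cfg$het_af_low) return(NA_character_)
  if (af <= cfg$hom_af_high) return("0/1")
  "1/1"
}

#' Count reference-spanning reads at a locus
#'
#' Number of passing primary alignments whose reference span covers
#' `[pos - flank, pos + flank]` and that contributed no signature to the
#' cluster under consideration. Reads soft-clipped at the event do not span
#' the window and are therefore not counted on either side.
#'
#' @param chrom,pos locus (0-based position).
#' @param spans the spanning-read index from [scan_alignments()].
#' @param member_reads read names already supporting the cluster.
#' @param flank half-width of the window in bp.
#' @return integer count.
#' @export
count_reference_spanning <- function(chrom, pos, spans, member_reads,
                                     flank = 500L) {
  if (nrow(spans) == 0L) return(0L)
  hit <- spans$chrom == chrom &
    spans$ref_start <= pos - flank &
    spans$ref_end >= pos + flank &
    !(spans$read_name %in% member_reads)
  sum(hit)
}

.vcf_header <- function(contigs, contig_lengths, sample = "SAMPLE",
                        fixed_date = FALSE) {
  date <- if (fixed_date) "20240101" else format(Sys.Date(), "%Y%m%d")
  c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", date),
    "##source=mevcall",
    paste0("##contig=<ID=", contigs, ",length=", contig_lengths, ">"),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=MECLASS,Number=1,Type=String,Description=\"Mobile element class (Alu, L1, SVA; none for ordinary SVs)\">",
    "##INFO=<ID=CROUND,Number=1,Type=String,Description=\"Classification round (first: template alignment; second: k-mer/plugin)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reference-spanning read count\">",
    "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Variant-supporting read count\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
}

#' Write genotyped mobile element variant calls as VCF 4.2
#'
#' INS records use `REF` = the reference base before the insertion point and
#' `ALT` = `REF` followed by the consensus sequence. DEL records default to
#' the symbolic `<DEL>` allele with `END`; with
#' `explicit_del_alleles = TRUE`, `REF` = anchor base plus deleted sequence
#' and `ALT` = anchor base. `POS` is the 1-based position of the anchor base
#' in both cases. Output is deterministic; `fixed_date = TRUE` freezes the
#' header date so identical runs are byte-identical.
#'
#' @param calls data frame of calls with columns `chrom`, `pos` (0-based
#'   event position), `svtype`, `svlen` (signed), `me_class`, `gt`, `dr`,
#'   `dv`, `consensus_sequence`, `classification_round`; must be sorted by
#'   `(chrom, pos)`.
#' @param reference genome accessor ([load_reference()]).
#' @param out_path output file path (plain text, bgzip-compatible).
#' @param sample sample name for the single sample column.
#' @param explicit_del_alleles write deletion alleles explicitly instead of
#'   symbolically.
#' @param fixed_date freeze the `##fileDate` header for reproducible bytes.
#' @return `out_path`, invisibly.
#' @export
write_mev_vcf <- function(calls, reference, out_path, sample = "SAMPLE",
                          explicit_del_alleles = FALSE, fixed_date = FALSE) {
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos)
    if (!identical(ord, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, pos)")
    }
  }
  header <- .vcf_header(names(reference), nchar(reference), sample,
                        fixed_date = fixed_date)
  lines <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    chrom <- calls$chrom[i]
    pos0 <- calls$pos[i]
    if (pos0 < 1L || pos0 >= nchar(reference[[chrom]])) {
      stop("call position ", pos0, " outside reference ", chrom)
    }
    anchor <- .ref_substring(reference, chrom, pos0 - 1L, pos0)
    svtype <- calls$svtype[i]
    svlen <- calls$svlen[i]
    if (svtype == "INS") {
      ref_allele <- anchor
      alt_allele <- paste0(anchor, calls$consensus_sequence[i])
      end <- pos0  # 1-based END == POS for insertions
    } else {
      if (explicit_del_alleles) {
        ref_allele <- paste0(anchor,
                             .ref_substring(reference, chrom, pos0,
                                            pos0 + abs(svlen)))
        alt_allele <- anchor
      } else {
        ref_allele <- anchor
        alt_allele <- "<DEL>"
      }
      end <- pos0 + abs(svlen)
    }
    info <- paste0("SVTYPE=", svtype, ";SVLEN=", svlen, ";END=", end,
                   ";MECLASS=", calls$me_class[i],
                   ";CROUND=", calls$classification_round[i])
    lines[i] <- paste(chrom, pos0, paste0("mev_", svtype, "_", i), ref_allele,
                      alt_allele, ".", "PASS", info, "GT:DR:DV",
                      paste(calls$gt[i], calls$dr[i], calls$dv[i], sep = ":"),
                      sep = "\t")
  }
  writeLines(c(header, lines), out_path)
  invisible(out_path)
}

#' Read a (single-sample) SV VCF into a call table
#'
#' Light parser for VCFs written by [write_mev_vcf()] and for simulator truth
#' VCFs: extracts `chrom`, `pos` (1-based as printed), `svtype`, `svlen`,
#' `me_class` (`"none"` when absent) and `gt`.
#'
#' @param path VCF file.
#' @return data frame, one row per record, sorted as in the file.
#' @export
read_mev_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      svtype = character(0), svlen = integer(0),
                      me_class = character(0), gt = character(0),
                      stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  rows <- lapply(fields, function(f) {
    if (length(f) < 8L) stop("malformed VCF record: ", paste(f, collapse = "\t"))
    info <- f[8]
    svtype <- get_info(info, "SVTYPE")
    svlen <- suppressWarnings(as.integer(get_info(info, "SVLEN")))
    mecl <- get_info(info, "MECLASS")
    gt <- NA_character_
    if (length(f) >= 10L) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt)
      if (!is.na(gi)) gt <- smp[gi]
    }
    if (is.na(svtype) || is.na(svlen)) {
      stop("VCF record at ", f[1], ":", f[2],
           " lacks SVTYPE/SVLEN INFO keys")
    }
    data.frame(chrom = f[1], pos = as.integer(f[2]), svtype = svtype,
               svlen = svlen,
               me_class = if (is.na(mecl)) "none" else mecl,
               gt = gt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
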