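#' Simulation parameters
#'
#' Describes an in-silico diploid genome with implanted mobile element
#' insertions (MEI), mobile element deletions (MED) and ordinary structural
#' variants, and the long-read sampling from it. Defaults describe the
#' desk-scale benchmark design: a 1 Mb genome, 30 MEIs and 30 MEDs per class
#' plus 60 ordinary SVs, 30x HiFi-like reads.
#'
#' @param genome_length random backbone length (bp) of the reference.
#' @param n_mei_per_class,n_med_per_class implanted MEI/MED count per ME
#'   class (Alu, L1, SVA).
#' @param n_ordinary_sv count of ordinary SVs (half random-sequence
#'   insertions, half random-interval deletions, 50-2000 bp).
#' @param het_fraction probability an event is heterozygous (on one
#'   haplotype); otherwise homozygous (both).
#' @param depth total fold coverage across the haplotype pair.
#' @param read_length_mean,read_length_sd Normal read length parameters (bp),
#'   truncated below at 500 bp.
#' @param error_model `"hifi_like"` (substitution 0.002, indel 0.0005) or
#'   `"ont_like"` (0.02 / 0.02); `substitution_rate`/`indel_rate` override.
#' @param substitution_rate,indel_rate per-base error rates; `NULL` takes the
#'   `error_model` defaults.
#' @param l1_truncation 5'-truncate implanted L1 copies to a uniform fraction
#'   in `[0.3, 1]` of the template (the hallmark of real L1 insertions).
#' @param mei_fragment_fraction fraction of MEIs (all classes) implanted as
#'   heavily truncated fragments, uniform in `fragment_range` of the
#'   template; used by the ablation benchmark.
#' @param fragment_range length-fraction range of fragment MEIs.
#' @param mei_divergence per-base substitution divergence of implanted
#'   element copies from their template (default 2%).
#' @param polyA_mean mean of the geometric polyA tail appended to element
#'   copies.
#' @param split_del_threshold deletions at least this long split a read into
#'   primary + supplementary placements (SA tags) instead of one `D` op.
#' @param seed integer RNG seed; identical parameters and seed give
#'   byte-identical outputs.
#' @return object of class `SimParams`.
#' @export
sim_params <- function(genome_length = 1000000L,
                       n_mei_per_class = 30L,
                       n_med_per_class = 30L,
                       n_ordinary_sv = 60L,
                       het_fraction = 0.5,
                       depth = 30,
                       read_length_mean = 10000L,
                       read_length_sd = 1500L,
                       error_model = c("hifi_like", "ont_like"),
                       substitution_rate = NULL,
                       indel_rate = NULL,
                       l1_truncation = TRUE,
                       mei_fragment_fraction = 0,
                       fragment_range = c(0.35, 0.5),
                       mei_divergence = 0.02,
                       polyA_mean = 30L,
                       split_del_threshold = 5000L,
                       seed = 1L) {
  error_model <- match.arg(error_model)
  if (is.null(substitution_rate)) {
    substitution_rate <- if (error_model == "hifi_like") 0.002 else 0.02
  }
  if (is.null(indel_rate)) {
    indel_rate <- if (error_model == "hifi_like") 0.0005 else 0.02
  }
  p <- list(genome_length = as.integer(genome_length),
            n_mei_per_class = as.integer(n_mei_per_class),
            n_med_per_class = as.integer(n_med_per_class),
            n_ordinary_sv = as.integer(n_ordinary_sv),
            het_fraction = het_fraction,
            depth = depth,
            read_length_mean = as.integer(read_length_mean),
            read_length_sd = as.integer(read_length_sd),
            error_model = error_model,
            substitution_rate = substitution_rate,
            indel_rate = indel_rate,
            l1_truncation = isTRUE(l1_truncation),
            mei_fragment_fraction = mei_fragment_fraction,
            fragment_range = fragment_range,
            mei_divergence = mei_divergence,
            polyA_mean = as.integer(polyA_mean),
            split_del_threshold = as.integer(split_del_threshold),
            seed = as.integer(seed))
  if (p$genome_length <= 10L * p$read_length_mean) {
    stop("genome_length must exceed 10 x read_length_mean")
  }
  if (any(c(p$n_mei_per_class, p$n_med_per_class, p$n_ordinary_sv) < 0L)) {
    stop("event counts must be >= 0")
  }
  if (p$substitution_rate < 0 || p$substitution_rate > 0.3 ||
      p$indel_rate < 0 || p$indel_rate > 0.3) {
    stop("error rates must be in [0, 0.3]")
  }
  if (p$het_fraction < 0 || p$het_fraction > 1) {
    stop("het_fraction must be in [0, 1]")
  }
  class(p) <- "SimParams"
  p
}

BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute each base with probability rate (always to a different base)
.diverge <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

# one implanted mobile element copy: optionally 5'-truncated template
# + polyA tail + divergence
.me_copy <- function(template_seq, params, fragment = FALSE,
                     truncate_l1 = FALSE) {
  n <- nchar(template_seq)
  frac <- 1
  if (fragment) {
    frac <- stats::runif(1, params$fragment_range[1], params$fragment_range[2])
  } else if (truncate_l1) {
    frac <- stats::runif(1, 0.3, 1)
  }
  keep <- max(1L, as.integer(round(frac * n)))
  body <- substring(template_seq, n - keep + 1L, n)  # 5' truncation keeps 3' end
  tail_len <- stats::rgeom(1, 1 / (params$polyA_mean + 1))
  .diverge(paste0(body, strrep("A", tail_len)), params$mei_divergence)
}

.plan_events <- function(params, lib) {
  ev <- list()
  add <- function(kind, class, seq = NULL, len = NULL) {
    ev[[length(ev) + 1L]] <<- list(kind = kind, me_class = class,
                                   seq = seq, len = len)
  }
  for (cls in ME_CLASSES) {
    tmpl <- templates_of_class(lib, cls)
    if (nrow(tmpl) == 0L &&
        (params$n_mei_per_class > 0L || params$n_med_per_class > 0L)) {
      stop("library has no template of class ", cls)
    }
    for (i in seq_len(params$n_mei_per_class)) {
      ti <- sample(nrow(tmpl), 1L)
      frag <- stats::runif(1) < params$mei_fragment_fraction
      seq <- .me_copy(tmpl$sequence[ti], params, fragment = frag,
                      truncate_l1 = !frag && cls == "L1" && params$l1_truncation)
      add("MEI", cls, seq = seq)
    }
    for (i in seq_len(params$n_med_per_class)) {
      ti <- sample(nrow(tmpl), 1L)
      seq <- .me_copy(tmpl$sequence[ti], params,
                      truncate_l1 = cls == "L1" && params$l1_truncation)
      add("MED", cls, seq = seq)
    }
  }
  n_ins <- ceiling(params$n_ordinary_sv / 2)
  for (i in seq_len(params$n_ordinary_sv)) {
    len <- as.integer(round(stats::runif(1, 50, 2000)))
    if (i <= n_ins) add("ordINS", "none", seq = .random_dna(len))
    else add("ordDEL", "none", len = len)
  }
  if (length(ev)) ev <- ev[sample(length(ev))]  # random genomic order
  ev
}

#' Simulate a diploid genome with implanted mobile element variants
#'
#' The reference is i.i.d. uniform random DNA into which one element copy per
#' MED is embedded (so the deletion allele removes real element content).
#' MEIs insert an element copy into the carrier haplotype(s); ordinary SVs
#' are random-sequence insertions and random-interval deletions of
#' 50-2000 bp. Each event is heterozygous with probability `het_fraction`
#' (carrier haplotype chosen at random), otherwise homozygous. Event anchors
#' are laid out left to right with at least 3 kb between the end of one event
#' footprint and the next anchor, so neighbouring events never interact.
#'
#' @param params a [sim_params()].
#' @param lib an `MELibrary` (defaults to the built-in toy library).
#' @return list with `reference` (named character vector, chromosome
#'   `simchr1`), `hap1`/`hap2` (each `list(seq, blocks)` where `blocks` maps
#'   haplotype intervals to reference intervals), and `truth` (data frame:
#'   `chrom`, `pos` 0-based anchor, `svtype`, `svlen` signed, `me_class`,
#'   `gt`, `seq`).
#' @export
simulate_genome <- function(params, lib = builtin_me_library()) {
  set.seed(params$seed)
  events <- .plan_events(params, lib)
  n <- length(events)
  sep <- 3000L
  margin <- as.integer(1.5 * params$read_length_mean)
  gap_min <- if (n > 0) c(margin, rep(sep, n - 1L), margin) else params$genome_length
  slack <- params$genome_length - sum(gap_min)
  if (slack < 0) {
    stop("genome too small to host ", n, " events with ", sep,
         " bp separation: need > ", sum(gap_min), " bp")
  }
  extra <- if (n > 0) diff(c(0, sort(stats::runif(n, 0, slack)), slack)) else 0
  gaps <- as.integer(round(gap_min + extra))

  chunks <- character(0)
  truth <- vector("list", n)
  cursor <- 0L
  for (i in seq_len(n)) {
    g <- gaps[i]
    chunks <- c(chunks, .random_dna(g))
    cursor <- cursor + g
    e <- events[[i]]
    gt <- if (stats::runif(1) < params$het_fraction) {
      sample(c("1|0", "0|1"), 1L)
    } else "1|1"
    if (e$kind %in% c("MED", "ordDEL")) {
      content <- if (e$kind == "MED") e$seq else .random_dna(e$len)
      chunks <- c(chunks, content)
      truth[[i]] <- data.frame(
        chrom = "simchr1", pos = cursor, svtype = "DEL",
        svlen = -nchar(content), me_class = e$me_class, gt = gt,
        seq = content, stringsAsFactors = FALSE)
      cursor <- cursor + nchar(content)
    } else {
      truth[[i]] <- data.frame(
        chrom = "simchr1", pos = cursor, svtype = "INS",
        svlen = nchar(e$seq), me_class = e$me_class, gt = gt,
        seq = e$seq, stringsAsFactors = FALSE)
    }
  }
  chunks <- c(chunks, .random_dna(gaps[n + 1L]))
  reference <- paste(chunks, collapse = "")
  truth <- if (n > 0) do.call(rbind, truth) else
    data.frame(chrom = character(0), pos = integer(0), svtype = character(0),
               svlen = integer(0), me_class = character(0), gt = character(0),
               seq = character(0), stringsAsFactors = FALSE)

  hap1 <- .build_haplotype(reference, truth, hap = 1L)
  hap2 <- .build_haplotype(reference, truth, hap = 2L)
  ref <- c(simchr1 = reference)
  list(reference = ref, hap1 = hap1, hap2 = hap2, truth = truth,
       params = params)
}

# Apply the events carried by one haplotype to the reference; returns the
# haplotype sequence plus a block table mapping haplotype coordinates back
# to reference coordinates (types: M = copied reference, I = inserted
# sequence anchored at a reference position).
.build_haplotype <- function(reference, truth, hap) {
  carried <- if (nrow(truth)) {
    substr(truth$gt, ifelse(hap == 1L, 1L, 3L), ifelse(hap == 1L, 1L, 3L)) == "1"
  } else logical(0)
  ev <- truth[carried, , drop = FALSE]
  ev <- ev[order(ev$pos), , drop = FALSE]
  ref_len <- nchar(reference)
  pieces <- character(0)
  blocks <- list()
  hap_cursor <- 0L
  ref_cursor <- 0L
  add_block <- function(type, len, ref_start) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      type = type, hap_start = hap_cursor, len = len, ref_start = ref_start,
      stringsAsFactors = FALSE)
    hap_cursor <<- hap_cursor + len
  }
  for (i in seq_len(nrow(ev))) {
    m_len <- ev$pos[i] - ref_cursor
    if (m_len > 0L) {
      pieces <- c(pieces, substring(reference, ref_cursor + 1L, ev$pos[i]))
      add_block("M", m_len, ref_cursor)
    }
    ref_cursor <- ev$pos[i]
    if (ev$svtype[i] == "INS") {
      pieces <- c(pieces, ev$seq[i])
      add_block("I", nchar(ev$seq[i]), ref_cursor)
    } else {
      ref_cursor <- ref_cursor + abs(ev$svlen[i])  # skip deleted interval
    }
  }
  if (ref_cursor < ref_len) {
    pieces <- c(pieces, substring(reference, ref_cursor + 1L, ref_len))
    add_block("M", ref_len - ref_cursor, ref_cursor)
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(type = character(0), hap_start = integer(0), len = integer(0),
               ref_start = integer(0), stringsAsFactors = FALSE)
  list(seq = paste(pieces, collapse = ""), blocks = blocks)
}

# Project read interval [start, start + len) of a haplotype onto the
# reference: a segment list of M pieces (with reference coordinates) and I
# pieces, with variant deletions implied by reference-coordinate gaps.
.project_read <- function(blocks, start, len) {
  end <- start + len
  first <- findInterval(start, blocks$hap_start)
  segs <- list()
  for (b in seq(first, nrow(blocks))) {
    bs <- blocks$hap_start[b]
    be <- bs + blocks$len[b]
    if (bs >= end) break
    lo <- max(bs, start); hi <- min(be, end)
    if (hi <= lo) next
    if (blocks$type[b] == "M") {
      segs[[length(segs) + 1L]] <- list(
        type = "M", len = hi - lo, ref_start = blocks$ref_start[b] + (lo - bs))
    } else {
      segs[[length(segs) + 1L]] <- list(type = "I", len = hi - lo)
    }
  }
  segs
}

.unphase_gt <- function(gt) ifelse(gt == "1|1", "1/1", "0/1")

# CIGAR assembly for one read from its segment list, with sequencing errors.
# Returns NULL when the read has no reference-anchored base, otherwise a list
# (ref_start, cigar ops as op/len vectors, seq).
.read_alignment <- function(segs, seq, sub_rate, indel_rate) {
  types <- vapply(segs, `[[`, character(1), "type")
  if (!any(types == "M")) return(NULL)

  # per-base representation: op ("M"/"I") and D-gap before each base
  lens <- vapply(segs, `[[`, numeric(1), "len")
  op <- rep(types, lens)
  L <- length(op)
  dbefore <- integer(L)
  ref_start <- NA_integer_
  ref_cursor <- NA_integer_
  base_i <- 1L
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (s$type == "M") {
      if (is.na(ref_start)) {
        ref_start <- s$ref_start
      } else {
        gap <- s$ref_start - ref_cursor
        if (gap > 0L) dbefore[base_i] <- dbefore[base_i] + gap
      }
      ref_cursor <- s$ref_start + s$len
    }
    base_i <- base_i + s$len
  }

  bases <- strsplit(seq, "")[[1]]
  stopifnot(length(bases) == L)

  if (sub_rate > 0) {
    hit <- which(stats::runif(L) < sub_rate)
    for (i in hit) bases[i] <- sample(setdiff(BASES, bases[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(L) < indel_rate)
    is_del <- stats::runif(length(hit)) < 0.5
    del_idx <- hit[is_del]
    ins_idx <- hit[!is_del]
    keep <- rep(TRUE, L)
    if (length(del_idx)) keep[del_idx] <- FALSE
    # deleted M bases become D gaps attached to the next kept base
    w <- dbefore + as.integer(!keep & op == "M")
    cs <- c(0L, cumsum(w))
    kept_idx <- which(keep)
    # D before kept base j = sum of w over (previous kept base, j]
    prev <- c(0L, kept_idx[-length(kept_idx)])
    new_db <- cs[kept_idx + 1L] - cs[prev + 1L]
    bases <- bases[kept_idx]
    op <- op[kept_idx]
    dbefore <- new_db
    # insertion errors: one extra random base after each hit position still kept
    ins_idx <- ins_idx[keep[ins_idx]]
    ins_after <- match(ins_idx, kept_idx)
    ins_after <- ins_after[!is.na(ins_after)]
    if (length(ins_after)) {
      key <- c(seq_along(op), ins_after + 0.5)
      ordk <- order(key)
      bases <- c(bases, sample(BASES, length(ins_after), replace = TRUE))[ordk]
      op <- c(op, rep("I", length(ins_after)))[ordk]
      dbefore <- c(dbefore, integer(length(ins_after)))[ordk]
    }
  }
  L <- length(op)
  if (L == 0L || !any(op == "M")) return(NULL)

  # trailing D gaps never arise (dbefore attaches to a base); leading D on
  # the first base would mean the read starts with a deletion: shift start.
  if (dbefore[1L] > 0L) {
    ref_start <- ref_start + dbefore[1L]
    dbefore[1L] <- 0L
  }
  # token stream: optional D before each base, then the base's op
  has_d <- which(dbefore > 0L)
  key <- c(seq_len(L), has_d - 0.5)
  ordk <- order(key)
  tok_op <- c(op, rep("D", length(has_d)))[ordk]
  tok_len <- c(rep(1L, L), dbefore[has_d])[ordk]
  # run-length compress
  grp <- cumsum(c(TRUE, tok_op[-1L] != tok_op[-length(tok_op)]))
  run_op <- tok_op[!duplicated(grp)]
  run_len <- as.integer(tapply(tok_len, grp, sum))

  # leading/trailing insertions become soft clips; leading/trailing D dropped
  while (length(run_op) && run_op[1L] == "D") {
    ref_start <- ref_start + run_len[1L]
    run_op <- run_op[-1L]; run_len <- run_len[-1L]
  }
  while (length(run_op) && run_op[length(run_op)] == "D") {
    run_op <- run_op[-length(run_op)]; run_len <- run_len[-length(run_len)]
  }
  if (length(run_op) && run_op[1L] == "I") run_op[1L] <- "S"
  if (length(run_op) && run_op[length(run_op)] == "I") run_op[length(run_op)] <- "S"
  if (!any(run_op == "M")) return(NULL)

  list(ref_start = ref_start, op = run_op, len = run_len,
       seq = paste(bases, collapse = ""))
}

# Split a read alignment at D ops >= threshold into SAM placements.
# Returns a data frame of placements (ref_start, cigar, is_supp).
.split_placements <- function(aln, threshold) {
  op <- aln$op; len <- aln$len
  big <- which(op == "D" & len >= threshold)
  qlen <- sum(len[op %in% c("M", "I", "S")])
  if (length(big) == 0L) {
    return(data.frame(ref_start = aln$ref_start,
                      cigar = paste0(len, op, collapse = ""),
                      qspan = qlen, is_supp = FALSE,
                      stringsAsFactors = FALSE))
  }
  bounds <- c(0L, big, length(op) + 1L)
  segs <- list()
  for (s in seq_len(length(big) + 1L)) {
    idx <- seq(bounds[s] + 1L, bounds[s + 1L] - 1L)
    sop <- op[idx]; slen <- len[idx]
    # query offset and ref offset of this piece
    before <- seq_len(bounds[s])
    before <- before[before <= length(op)]
    q_off <- sum(len[before][op[before] %in% c("M", "I", "S")])
    r_off <- sum(len[before][op[before] %in% c("M", "D")])
    # clip the query outside the piece
    q_here <- sum(slen[sop %in% c("M", "I", "S")])
    lead <- q_off
    trail <- qlen - q_off - q_here
    cig <- character(0)
    if (lead > 0L) { sop <- c("S", sop); slen <- c(lead, slen) }
    if (trail > 0L) { sop <- c(sop, "S"); slen <- c(slen, trail) }
    segs[[s]] <- data.frame(ref_start = aln$ref_start + r_off,
                            cigar = paste0(slen, sop, collapse = ""),
                            qspan = q_here, is_supp = NA,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  out$is_supp <- seq_len(nrow(out)) != which.max(out$qspan)
  out
}

#' Simulate long reads and their reference alignments
#'
#' Reads are sampled uniformly from each haplotype at `depth / 2` fold
#' coverage per haplotype, with Normal lengths truncated at 500 bp.
#' Sequencing errors are injected per base (substitutions plus 1 bp
#' insertion/deletion errors). Each read's alignment to the reference is
#' computed analytically from the haplotype-to-reference block map — no
#' aligner runs: implanted insertions become `I` operations, deletions `D`
#' operations, and deletions of at least `split_del_threshold` split the
#' read into primary + supplementary placements with reciprocal SA tags.
#' Reads falling entirely inside an inserted sequence have no reference
#' anchor and are dropped. Output is a coordinate-sorted SAM.
#'
#' @param sim result of [simulate_genome()].
#' @param params the same [sim_params()].
#' @param sam_path output SAM path.
#' @param fastq_path optional FASTQ output (reads in sequencing orientation).
#' @return invisible list with `sam_path`, `n_reads` (emitted reads) and
#'   `n_records` (SAM records including supplementary placements).
#' @export
simulate_reads <- function(sim, params, sam_path, fastq_path = NULL) {
  set.seed(params$seed + 1L)
  ref_len <- nchar(sim$reference[[1]])
  records <- list()
  fastq <- character(0)
  n_reads <- 0L

  for (h in 1:2) {
    hap <- sim[[paste0("hap", h)]]
    hap_len <- nchar(hap$seq)
    n <- as.integer(round((params$depth / 2) * hap_len / params$read_length_mean))
    if (n <= 0L) next
    lens <- pmax(500L, as.integer(round(stats::rnorm(n, params$read_length_mean,
                                                     params$read_length_sd))))
    lens <- pmin(lens, hap_len)
    starts <- vapply(lens, function(l) {
      as.integer(floor(stats::runif(1, 0, hap_len - l + 1)))
    }, integer(1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (r in seq_len(n)) {
      qname <- sprintf("hap%d_read%05d", h, r)
      seq <- substring(hap$seq, starts[r] + 1L, starts[r] + lens[r])
      segs <- .project_read(hap$blocks, starts[r], lens[r])
      aln <- .read_alignment(segs, seq, params$substitution_rate,
                             params$indel_rate)
      if (is.null(aln)) next
      n_reads <- n_reads + 1L
      plc <- .split_placements(aln, params$split_del_threshold)
      flag_strand <- if (strands[r] == "-") .FLAG_REVERSE else 0L
      sa_all <- paste0("simchr1,", plc$ref_start + 1L, ",", strands[r], ",",
                       plc$cigar, ",60,0;")
      for (p in seq_len(nrow(plc))) {
        flag <- flag_strand + if (plc$is_supp[p]) .FLAG_SUPPLEMENTARY else 0L
        tags <- if (nrow(plc) > 1L) {
          paste0("\tSA:Z:", paste(sa_all[-p], collapse = ""))
        } else ""
        records[[length(records) + 1L]] <- list(
          pos = plc$ref_start[p],
          line = paste0(qname, "\t", flag, "\tsimchr1\t", plc$ref_start[p] + 1L,
                        "\t60\t", plc$cigar[p], "\t*\t0\t0\t", aln$seq,
                        "\t*", tags))
      }
      if (!is.null(fastq_path)) {
        out_seq <- if (strands[r] == "-") revcomp(aln$seq) else aln$seq
        fastq <- c(fastq, paste0("@", qname), out_seq, "+",
                   strrep("I", nchar(out_seq)))
      }
    }
  }
  pos <- vapply(records, `[[`, numeric(1), "pos")
  lines <- vapply(records, `[[`, character(1), "line")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:simchr1\tLN:", ref_len),
              "@PG\tID:mevcall-sim\tPN:mevcall-sim")
  writeLines(c(header, lines[order(pos)]), sam_path)
  if (!is.null(fastq_path)) writeLines(fastq, fastq_path)
  invisible(list(sam_path = sam_path, n_reads = n_reads,
                 n_records = length(records)))
}

#' Write the simulator's ground truth as a VCF
#'
#' @param truth truth data frame from [simulate_genome()].
#' @param reference the simulated reference accessor.
#' @param out_path output VCF path.
#' @return `out_path`, invisibly.
#' @export
write_truth_vcf <- function(truth, reference, out_path) {
  calls <- truth
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  calls$gt <- .unphase_gt(calls$gt)
  calls$dr <- 0L
  calls$dv <- 0L
  calls$consensus_sequence <- ifelse(calls$svtype == "INS", calls$seq, "")
  calls$classification_round <- "truth"
  write_mev_vcf(calls, reference, out_path, sample = "TRUTH",
                fixed_date = TRUE)
}

#' Simulate a complete dataset on disk
#'
#' Runs [simulate_genome()] and [simulate_reads()] and writes `ref.fa`,
#' `truth.vcf` and `reads.sam` (optionally `reads.fq`) under `out_dir`.
#'
#' @param params a [sim_params()].
#' @param lib an `MELibrary`.
#' @param out_dir output directory (created if needed).
#' @param fastq also write a FASTQ of the reads.
#' @return list with file paths, the truth data frame and the genome
#'   simulation object.
#' @export
simulate_dataset <- function(params, lib = builtin_me_library(),
                             out_dir = tempfile("sim"), fastq = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(params, lib)
  ref_path <- file.path(out_dir, "ref.fa")
  x <- Biostrings::DNAStringSet(sim$reference)
  names(x) <- names(sim$reference)
  Biostrings::writeXStringSet(x, ref_path, width = 60L)
  truth_path <- file.path(out_dir, "truth.vcf")
  write_truth_vcf(sim$truth, sim$reference, truth_path)
  sam_path <- file.path(out_dir, "reads.sam")
  fq <- if (fastq) file.path(out_dir, "reads.fq") else NULL
  rd <- simulate_reads(sim, params, sam_path, fq)
  list(ref = ref_path, truth_vcf = truth_path, sam = sam_path,
       fastq = fq, truth = sim$truth, sim = sim, params = params,
       n_reads = rd$n_reads)
}

#' Simulate a trio (two parents and a composed child)
#'
#' Both parents' variants are laid out on one shared reference (each parent
#' carries its own private events; deleted-element content for either parent
#' is embedded in the common reference). The child genome is composed of one
#' haplotype transmitted from each parent, so every child variant obeys
#' Mendelian transmission by construction; discordance measured on the
#' resulting callsets is caller error.
#'
#' @param params a [sim_params()]; event counts apply per parent.
#' @param lib an `MELibrary`.
#' @param out_dir output directory; `father/`, `mother/`, `child/`
#'   subdirectories are created.
#' @return list of the three dataset descriptors plus the transmitted
#'   haplotype indices.
#' @export
simulate_trio <- function(params, lib = builtin_me_library(),
                          out_dir = tempfile("trio")) {
  set.seed(params$seed)
  # one plan with both parents' events interleaved on a shared reference
  p2 <- params
  p2$n_mei_per_class <- 2L * params$n_mei_per_class
  p2$n_med_per_class <- 2L * params$n_med_per_class
  p2$n_ordinary_sv <- 2L * params$n_ordinary_sv
  p2$seed <- params$seed
  sim_all <- simulate_genome(p2, lib)
  truth <- sim_all$truth
  n <- nrow(truth)
  owner <- sample(rep(c("father", "mother"), length.out = n))

  set.seed(params$seed + 2L)
  out <- list()
  parent_truth <- list()
  for (who in c("father", "mother")) {
    t_par <- truth
    # events owned by the other parent are absent (0|0) here
    absent <- owner != who
    t_par$gt[absent] <- "0|0"
    t_par <- t_par[t_par$gt != "0|0", , drop = FALSE]
    parent_truth[[who]] <- t_par
  }
  transmitted <- list(father = sample(1:2, 1L), mother = sample(1:2, 1L))

  # child truth: transmitted allele from each parent
  child_rows <- list()
  for (who in c("father", "mother")) {
    t_par <- parent_truth[[who]]
    hap_idx <- transmitted[[who]]
    carried <- substr(t_par$gt, ifelse(hap_idx == 1L, 1L, 3L),
                      ifelse(hap_idx == 1L, 1L, 3L)) == "1"
    t_c <- t_par[carried, , drop = FALSE]
    if (nrow(t_c)) {
      t_c$gt <- if (who == "father") "1|0" else "0|1"
      child_rows[[who]] <- t_c
    }
  }
  child_truth <- do.call(rbind, child_rows)
  # merge duplicated loci (impossible here: parents have disjoint events)
  child_truth <- child_truth[order(child_truth$pos), , drop = FALSE]
  rownames(child_truth) <- NULL

  members <- list(father = parent_truth$father, mother = parent_truth$mother,
                  child = child_truth)
  seeds <- c(father = 11L, mother = 22L, child = 33L)
  for (who in names(members)) {
    d <- file.path(out_dir, who)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sim_i <- list(reference = sim_all$reference,
                  hap1 = .build_haplotype(sim_all$reference[[1]],
                                          members[[who]], 1L),
                  hap2 = .build_haplotype(sim_all$reference[[1]],
                                          members[[who]], 2L),
                  truth = members[[who]], params = params)
    ref_path <- file.path(d, "ref.fa")
    x <- Biostrings::DNAStringSet(sim_i$reference)
    names(x) <- names(sim_i$reference)
    Biostrings::writeXStringSet(x, ref_path, width = 60L)
    truth_path <- file.path(d, "truth.vcf")
    write_truth_vcf(sim_i$truth, sim_i$reference, truth_path)
    p_i <- params
    p_i$seed <- params$seed + seeds[[who]]
    sam_path <- file.path(d, "reads.sam")
    simulate_reads(sim_i, p_i, sam_path)
    out[[who]] <- list(ref = ref_path, truth_vcf = truth_path,
                       sam = sam_path, truth = sim_i$truth, sim = sim_i)
  }
  out$transmitted <- transmitted
  out
}
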