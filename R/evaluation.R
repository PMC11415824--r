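#' Precision, recall, F1
#'
#' Standard definitions with the 0/0 convention: a vanished denominator
#' yields 0 for the affected quantity.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `precision`, `recall`, `f1`.
#' @export
prf <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# greedy nearest-position matching between two call tables (same svtype
# assumed filtered by caller); each truth row used at most once.
# Returns integer vector: for each call row, the matched truth row or NA.
.greedy_match <- function(calls, truth, window, size_ratio) {
  nc <- nrow(calls); nt <- nrow(truth)
  match_of <- rep(NA_integer_, nc)
  if (nc == 0L || nt == 0L) return(match_of)
  pairs <- list()
  for (i in seq_len(nc)) {
    cand <- which(truth$chrom == calls$chrom[i] &
                    truth$svtype == calls$svtype[i] &
                    abs(truth$pos - calls$pos[i]) <= window)
    for (j in cand) {
      la <- abs(calls$svlen[i]); lb <- abs(truth$svlen[j])
      if (min(la, lb) / max(la, lb) >= size_ratio) {
        pairs[[length(pairs) + 1L]] <- c(i, j, abs(truth$pos[j] - calls$pos[i]))
      }
    }
  }
  if (length(pairs) == 0L) return(match_of)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
  used_t <- rep(FALSE, nt)
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    if (is.na(match_of[i]) && !used_t[j]) {
      match_of[i] <- j
      used_t[j] <- TRUE
    }
  }
  match_of
}

#' Match a callset against truth records
#'
#' A call matches a truth record iff they share the SV type, their positions
#' differ by at most `window` bp and their sizes agree to within
#' `size_ratio` (min/max). Matching is greedy by position distance with each
#' truth record used at most once. Calls matching a truth locus but
#' disagreeing on ME class form their own false-positive category
#' (`fp_class`), reported separately from locus-level false positives
#' (`fp_locus`); with `class_strict = TRUE` they are excluded from `tp`.
#'
#' @param calls,truth data frames with columns `chrom`, `pos`, `svtype`,
#'   `svlen`, `me_class`, `gt` (as from [read_mev_vcf()]).
#' @param window maximum position difference in bp.
#' @param size_ratio minimum min/max size ratio.
#' @param class_strict require ME class agreement for a TP.
#' @return list with counts `tp`, `fp`, `fn`, `fp_class`, `fp_locus`, the
#'   matched pair table `pairs` (`call_row`, `truth_row`, `class_match`,
#'   `gt_match`), and `metrics` (precision/recall/f1 plus `fdr`).
#' @export
match_calls <- function(calls, truth, window = 1000L, size_ratio = 0.7,
                        class_strict = FALSE) {
  match_of <- .greedy_match(calls, truth, window, size_ratio)
  matched <- which(!is.na(match_of))
  class_match <- vapply(matched, function(i) {
    calls$me_class[i] == truth$me_class[match_of[i]]
  }, logical(1))
  norm_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(g == "1/0", "0/1", g)
  }
  gt_match <- vapply(matched, function(i) {
    identical(norm_gt(calls$gt[i]), norm_gt(truth$gt[match_of[i]]))
  }, logical(1))
  fp_locus <- sum(is.na(match_of))
  fp_class <- sum(!class_match)
  if (class_strict) {
    tp <- sum(class_match)
    fp <- fp_locus + fp_class
  } else {
    tp <- length(matched)
    fp <- fp_locus
  }
  fn <- nrow(truth) - length(matched)
  m <- prf(tp, fp, fn)
  m$fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  list(tp = tp, fp = fp, fn = fn, fp_class = fp_class, fp_locus = fp_locus,
       pairs = data.frame(call_row = matched, truth_row = match_of[matched],
                          class_match = class_match, gt_match = gt_match),
       metrics = m)
}

#' Benchmark a callset against simulator truth
#'
#' Computes the benchmark panel: presence precision/recall/F1 (locus, type
#' and size agreement only), class-aware F1, genotype-aware F1 (a TP
#' additionally requires ME class and genotype agreement), FDR, and a
#' per-class breakdown. Truth records of ordinary SVs (`me_class == "none"`)
#' are excluded from the MEV truth set but calls landing on them are counted
#' as false positives, which is what makes the FDR meaningful.
#'
#' @param calls call table ([read_mev_vcf()]); normally only ME-classified
#'   calls.
#' @param truth truth table including ordinary SVs.
#' @param window,size_ratio matching parameters.
#' @param svtype optional restriction (`"INS"` or `"DEL"`) applied to both
#'   sides.
#' @return list of class `EvalResult`.
#' @export
evaluate_calls <- function(calls, truth, window = 1000L, size_ratio = 0.7,
                           svtype = NULL) {
  if (!is.null(svtype)) {
    calls <- calls[calls$svtype == svtype, , drop = FALSE]
    truth <- truth[truth$svtype == svtype, , drop = FALSE]
  }
  mev_truth <- truth[truth$me_class != "none", , drop = FALSE]
  presence <- match_calls(calls, mev_truth, window, size_ratio,
                          class_strict = FALSE)
  classed <- match_calls(calls, mev_truth, window, size_ratio,
                         class_strict = TRUE)
  # genotype-aware: TP requires class AND genotype agreement
  gt_tp <- sum(classed$pairs$class_match & classed$pairs$gt_match)
  gt_fp <- classed$tp + classed$fp - gt_tp
  gt_fn <- nrow(mev_truth) - gt_tp
  gt <- prf(gt_tp, gt_fp, gt_fn)

  per_class <- lapply(ME_CLASSES, function(cl) {
    ct <- calls[calls$me_class == cl, , drop = FALSE]
    tt <- mev_truth[mev_truth$me_class == cl, , drop = FALSE]
    match_calls(ct, tt, window, size_ratio, class_strict = FALSE)$metrics
  })
  names(per_class) <- ME_CLASSES

  out <- list(
    n_calls = nrow(calls), n_truth = nrow(mev_truth),
    presence = presence$metrics,
    class_aware = classed$metrics,
    genotype = c(gt, list(tp = gt_tp, fp = gt_fp, fn = gt_fn)),
    fp_class = classed$fp_class,
    counts = list(tp = presence$tp, fp = presence$fp, fn = presence$fn),
    per_class = per_class
  )
  class(out) <- "EvalResult"
  out
}

#' @export
print.EvalResult <- function(x, ...) {
  fmt <- function(m) sprintf("P=%.4f R=%.4f F1=%.4f", m$precision, m$recall,
                             m$f1)
  cat("EvalResult:", x$n_calls, "calls vs", x$n_truth, "MEV truth records\n")
  cat("  presence: ", fmt(x$presence), " FDR=",
      sprintf("%.4f", x$presence$fdr), "\n", sep = "")
  cat("  class-aware: ", fmt(x$class_aware), "\n", sep = "")
  cat("  genotype-aware: ", fmt(x$genotype), "\n", sep = "")
  invisible(x)
}

# transmissible alleles per genotype string
.transmissible <- function(gt) {
  switch(gt,
         "0/0" = 0L, "0|0" = 0L,
         "0/1" = c(0L, 1L), "1/0" = c(0L, 1L),
         "0|1" = c(0L, 1L), "1|0" = c(0L, 1L),
         "1/1" = 1L, "1|1" = 1L,
         stop("unrecognised genotype: ", gt))
}

#' Trio Mendelian discordance
#'
#' Sites are the union of matched loci across the three callsets (matching
#' as in [match_calls()], greedy, chaining through the child's calls first);
#' an individual without a call at a matched site is `0/0`. A site is
#' discordant iff the child's genotype cannot be assembled from one
#' transmitted allele of each parent.
#'
#' @param child,father,mother call tables ([read_mev_vcf()]).
#' @param window,size_ratio matching parameters.
#' @return list of class `TrioResult`: `n_sites`, `n_discordant`, `mdr`, and
#'   `by_svtype` breakdown.
#' @export
mendelian_discordance <- function(child, father, mother, window = 1000L,
                                  size_ratio = 0.7) {
  tabs <- list(child = child, father = father, mother = mother)
  # build site list: start from the union, anchored on child then parents
  site_list <- list()
  used <- lapply(tabs, function(t) rep(FALSE, nrow(t)))
  for (anchor in names(tabs)) {
    ta <- tabs[[anchor]]
    for (i in seq_len(nrow(ta))) {
      if (used[[anchor]][i]) next
      site <- list(chrom = ta$chrom[i], pos = ta$pos[i], svtype = ta$svtype[i],
                   svlen = ta$svlen[i], gts = c(child = "0/0", father = "0/0",
                                                mother = "0/0"))
      for (who in names(tabs)) {
        t2 <- tabs[[who]]
        cand <- which(!used[[who]] & t2$chrom == site$chrom &
                        t2$svtype == site$svtype &
                        abs(t2$pos - site$pos) <= window)
        if (length(cand)) {
          la <- abs(t2$svlen[cand]); lb <- abs(site$svlen)
          ok <- pmin(la, lb) / pmax(la, lb) >= size_ratio
          cand <- cand[ok]
        }
        if (length(cand)) {
          j <- cand[which.min(abs(t2$pos[cand] - site$pos))]
          used[[who]][j] <- TRUE
          site$gts[[who]] <- t2$gt[j]
        }
      }
      site_list[[length(site_list) + 1L]] <- site
    }
  }
  n_sites <- length(site_list)
  disc <- vapply(site_list, function(site) {
    ch <- .transmissible(site$gts[["child"]])
    ch_counts <- switch(site$gts[["child"]],
                        "0/0" = 0L, "0|0" = 0L,
                        "1/1" = 2L, "1|1" = 2L,
                        1L)
    fa <- .transmissible(site$gts[["father"]])
    mo <- .transmissible(site$gts[["mother"]])
    ok <- any(outer(fa, mo, `+`) == ch_counts)
    !ok
  }, logical(1))
  svt <- vapply(site_list, `[[`, character(1), "svtype")
  by_svtype <- lapply(split(disc, svt), function(d) {
    list(n_sites = length(d), n_discordant = sum(d),
         mdr = if (length(d)) mean(d) else 0)
  })
  out <- list(n_sites = n_sites, n_discordant = sum(disc),
              mdr = if (n_sites) mean(disc) else 0,
              by_svtype = by_svtype)
  class(out) <- "TrioResult"
  out
}

#' @export
print.TrioResult <- function(x, ...) {
  cat("TrioResult:", x$n_discordant, "discordant of", x$n_sites,
      sprintf("sites (MDR = %.4f)\n", x$mdr))
  invisible(x)
}
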