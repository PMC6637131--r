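# Concordance metrics between two CNA profiles: per-base precision /
# recall / F1 over non-neutral bases, the >= 90% segmental-corroboration
# rule, and length/amplitude stratification.  All per-base quantities are
# computed by interval arithmetic; per-base vectors are never materialized.

.class_ranges <- function(profile, class) {
  p <- profile[profile$cna_class == class, , drop = FALSE]
  GenomicRanges::reduce(GenomicRanges::GRanges(
    norm_chrom(p$chrom), IRanges::IRanges(p$start, p$end)))
}

.overlap_width <- function(a, b) {
  sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
}

#' Per-base F1 between two CNA profiles
#'
#' A base is corroborated when both profiles assign it the same non-neutral
#' CNA type (gain or loss).  Precision is corroborated bases over the first
#' (predicted) profile's non-neutral bases, recall is corroborated bases
#' over the reference's non-neutral bases, and
#' `F1 = 2 p r / (p + r)`.  Neutral-vs-neutral bases do not enter the
#' score.  When both profiles are all-neutral the result is flagged
#' undefined (`f1 = NA`).
#'
#' @param predicted,reference segment data.frames with `chrom, start, end,
#'   cna_class` on the same genome.
#' @return list of class `"base_call_comparison"` with
#'   `corroborated_bases, total_bases, predicted_bases, reference_bases,
#'   precision, recall, f1`.
#' @export
per_base_f1 <- function(predicted, reference) {
  pg <- .class_ranges(predicted, "gain"); pl <- .class_ranges(predicted, "loss")
  rg <- .class_ranges(reference, "gain"); rl <- .class_ranges(reference, "loss")
  corr <- .overlap_width(pg, rg) + .overlap_width(pl, rl)
  pred_b <- sum(GenomicRanges::width(pg)) + sum(GenomicRanges::width(pl))
  ref_b <- sum(GenomicRanges::width(rg)) + sum(GenomicRanges::width(rl))
  union_b <- sum(GenomicRanges::width(GenomicRanges::union(pg, rg))) +
    sum(GenomicRanges::width(GenomicRanges::union(pl, rl)))
  out <- list(corroborated_bases = corr, total_bases = union_b,
              predicted_bases = pred_b, reference_bases = ref_b,
              precision = if (pred_b > 0) corr / pred_b else NA_real_,
              recall = if (ref_b > 0) corr / ref_b else NA_real_)
  out$f1 <- if (pred_b == 0 && ref_b == 0) {
    NA_real_  # both profiles all-neutral: undefined
  } else if (is.na(out$precision) || is.na(out$recall) ||
             out$precision + out$recall == 0) {
    0
  } else {
    2 * out$precision * out$recall / (out$precision + out$recall)
  }
  class(out) <- "base_call_comparison"
  out
}

#' @export
print.base_call_comparison <- function(x, ...) {
  cat(sprintf(
    "<base_call_comparison> precision %.4f  recall %.4f  F1 %s (%d corroborated / %d scored bases)\n",
    x$precision, x$recall,
    if (is.na(x$f1)) "undefined (all-neutral)" else sprintf("%.4f", x$f1),
    x$corroborated_bases, x$total_bases))
  invisible(x)
}

#' Is a segment corroborated by another profile?
#'
#' A non-neutral segment is corroborated when at least 90% of its bases
#' (inclusive threshold) receive the same CNA type from the other profile.
#' The comparison uses exact integer arithmetic at the boundary.
#'
#' @param segment one-row data.frame (or list) with `chrom, start, end,
#'   cna_class`; the class must be gain or loss.
#' @param other_profile segment data.frame to compare against.
#' @param threshold corroborated fraction required (default 0.90).
#' @return `TRUE` or `FALSE`.
#' @export
segment_corroborated <- function(segment, other_profile, threshold = 0.90) {
  cls <- segment$cna_class[1]
  if (!cls %in% c("gain", "loss"))
    stop("segment_corroborated expects a non-neutral segment")
  seg <- GenomicRanges::GRanges(norm_chrom(segment$chrom[1]),
                                IRanges::IRanges(segment$start[1], segment$end[1]))
  matched <- .overlap_width(seg, .class_ranges(other_profile, cls))
  len <- segment$end[1] - segment$start[1] + 1
  # integer-exact >= threshold test (threshold is a ratio of small integers)
  matched * 100 >= len * round(threshold * 100)
}

#' Stratify segments by length and amplitude
#'
#' Bins non-neutral segments by `floor(log10(length))` into
#' `{<3, [3,4), [4,5), [5,6), >=6}` and by `|mean_log2|` into low (< 1),
#' mid (\[1, 3)) and high (>= 3) amplitude.  When a second profile is
#' supplied each segment is additionally tested with
#' [segment_corroborated()] and match percentages are reported split at
#' 100 kb.
#'
#' @param segments segment data.frame with `chrom, start, end, cna_class,
#'   mean_log2`.
#' @param other_profile optional comparison profile.
#' @return list with `counts` (length-bin x amplitude-bin table) and, when
#'   a comparison profile is given, `match_lt_100kb`, `match_ge_100kb`
#'   (match fractions) and a per-segment `detail` data.frame.
#' @export
stratify_segments <- function(segments, other_profile = NULL) {
  len_labels <- c("<3", "[3,4)", "[4,5)", "[5,6)", ">=6")
  amp_labels <- c("low", "mid", "high")
  s <- segments[segments$cna_class %in% c("gain", "loss"), , drop = FALSE]
  if (nrow(s)) {
    len <- s$end - s$start + 1
    if (any(len <= 0)) stop("zero-length segment encountered")
    len_bin <- cut(log10(len), c(-Inf, 3, 4, 5, 6, Inf),
                   right = FALSE, labels = len_labels)
    amp_bin <- cut(abs(s$mean_log2), c(0, 1, 3, Inf),
                   right = FALSE, labels = amp_labels)
  } else {
    len <- numeric(0)
    len_bin <- factor(character(), levels = len_labels)
    amp_bin <- factor(character(), levels = amp_labels)
  }
  out <- list(counts = table(length_bin = len_bin, amplitude_bin = amp_bin))
  if (!is.null(other_profile)) {
    corro <- if (nrow(s)) vapply(seq_len(nrow(s)), function(i)
      segment_corroborated(s[i, ], other_profile), NA) else logical(0)
    focal <- len < 1e5
    out$match_lt_100kb <- if (any(focal)) mean(corro[focal]) else NA_real_
    out$match_ge_100kb <- if (any(!focal)) mean(corro[!focal]) else NA_real_
    out$detail <- data.frame(s[, c("chrom", "start", "end", "cna_class")],
                             length = len, length_bin = len_bin,
                             amplitude_bin = amp_bin, corroborated = corro)
  }
  out
}

#' Compare two CNA profiles
#'
#' Convenience wrapper: per-base F1 in both orientations (F1 is not exactly
#' symmetric because precision/recall swap roles) plus length/amplitude
#' stratification of the reference profile against the predicted one.
#'
#' @param predicted,reference segment data.frames or seg-table paths
#'   (read with [read_cna_table()]).
#' @return list with `f1`, `f1_reversed` and `strata`.
#' @export
compare_cna_profiles <- function(predicted, reference) {
  if (is.character(predicted)) predicted <- read_cna_table(predicted)
  if (is.character(reference)) reference <- read_cna_table(reference)
  list(f1 = per_base_f1(predicted, reference),
       f1_reversed = per_base_f1(reference, predicted),
       strata = stratify_segments(reference, predicted))
}
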