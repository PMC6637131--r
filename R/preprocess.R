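# Step 2 of the pipeline: blacklist filtering, coverage-range
# filtering, heterozygous-site identification, 100-bp window construction
# and diploid-baseline normalization.

#' Read a BED blacklist
#'
#' Minimal 0-based half-open BED reader with per-line validation; a
#' malformed line is fatal and reported with its line number.
#'
#' @param path BED file (first three columns chrom, start, end).
#' @return data.frame with columns `chrom, start, end` (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- strsplit(lines[idx], "[\t ]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (length(p) < 3L || is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED line ", idx[i], " in ", path, ": '", lines[idx[i]], "'")
  }
  data.frame(chrom = norm_chrom(vapply(parts, `[`, "", 1L)),
             start = vapply(parts, function(p) as.numeric(p[2]), 0),
             end = vapply(parts, function(p) as.numeric(p[3]), 0),
             stringsAsFactors = FALSE)
}

#' Remove blacklisted positions
#'
#' Drops every record whose 1-based position falls inside a blacklist
#' interval (BED 0-based half-open, so BED `start end` covers 1-based
#' positions `start+1 .. end`).  Record order is preserved.
#'
#' @param records variant-record data.frame.
#' @param blacklist BED path or a data.frame as returned by [read_bed()].
#' @return filtered records.
#' @export
apply_blacklist <- function(records, blacklist) {
  validate_records(records)
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  if (nrow(blacklist) == 0L || nrow(records) == 0L) return(records)
  bl <- GenomicRanges::GRanges(norm_chrom(blacklist$chrom),
                               IRanges::IRanges(blacklist$start + 1, blacklist$end))
  rc <- GenomicRanges::GRanges(norm_chrom(records$chrom),
                               IRanges::IRanges(records$pos, records$pos))
  hit <- GenomicRanges::countOverlaps(rc, bl) > 0L
  if (any(hit)) message("apply_blacklist: removed ", sum(hit), " record(s)")
  records[!hit, , drop = FALSE]
}

#' Coverage-range filter
#'
#' Keeps a record iff its normal-sample depth lies inside
#' `[median * min_factor, median * max_factor]` (bounds inclusive); on chrX
#' the `xmin_factor`/`xmax_factor` pair is substituted.  Positions outside
#' the range are ignored by the rest of the pipeline.
#'
#' @param records variant-record data.frame.
#' @param config a [cna_config()].
#' @param median_normal_coverage the median normal depth; defaults to the
#'   value stored in `config` and must be positive.
#' @return filtered records.
#' @export
coverage_filter <- function(records, config = cna_config(),
                            median_normal_coverage = config$median_normal_coverage) {
  validate_records(records)
  med <- median_normal_coverage
  if (is.null(med) || !is.finite(med) || med <= 0)
    stop("median normal coverage must be a positive number")
  chrom <- norm_chrom(records$chrom)
  is_x <- chrom == "X"
  lo <- ifelse(is_x, med * config$xmin_factor, med * config$min_factor)
  hi <- ifelse(is_x, med * config$xmax_factor, med * config$max_factor)
  keep <- records$normal_total >= lo & records$normal_total <= hi
  records[keep, , drop = FALSE]
}

#' Drop chromosomes outside the CNA model
#'
#' chrY and mitochondrial records are removed: the window/BAF model assumes
#' two germline haplotypes and the method addresses autosomes plus chrX.
#'
#' @param records variant-record data.frame.
#' @return filtered records.
#' @export
drop_nonmodel_chroms <- function(records) {
  keep <- !(norm_chrom(records$chrom) %in% c("Y", "MT"))
  records[keep, , drop = FALSE]
}

#' Identify germline-heterozygous sites
#'
#' A site is called heterozygous when the normal-sample BAF lies in
#' `[het_baf_min, het_baf_max]` (default `[0.30, 0.70]`, inclusive) with
#' normal depth at least `het_min_depth`.  Each het site records tumor and
#' normal BAFs and the site-level LOH `|baf_tumor - baf_normal|`.
#'
#' @param records blacklist- and coverage-filtered variant records.
#' @param config a [cna_config()].
#' @return data.frame with columns `chrom, pos, baf_tumor, baf_normal,
#'   site_loh`.
#' @export
call_heterozygous <- function(records, config = cna_config()) {
  validate_records(records)
  ok_depth <- records$normal_total >= config$het_min_depth &
    records$tumor_total > 0
  bn <- ifelse(records$normal_total > 0,
               records$normal_mutant / records$normal_total, NA_real_)
  het <- ok_depth & !is.na(bn) &
    bn >= config$het_baf_min & bn <= config$het_baf_max
  if (!any(het)) warning("no heterozygous sites identified")
  out <- data.frame(
    chrom = norm_chrom(records$chrom[het]),
    pos = records$pos[het],
    baf_tumor = records$tumor_mutant[het] / records$tumor_total[het],
    baf_normal = bn[het],
    stringsAsFactors = FALSE)
  out$site_loh <- abs(out$baf_tumor - out$baf_normal)
  rownames(out) <- NULL
  out
}

#' Build fixed-width coverage windows
#'
#' Groups records into fixed windows of `window_size` bases (default 100 bp):
#' window index `floor((pos - 1) / window_size)`, 1-based inclusive span
#' `[index * ws + 1, (index + 1) * ws]`.  A window's tumor/normal coverage
#' is the mean `tumor_total`/`normal_total` over its contributing sites;
#' windows with no variants are absent from the output.
#'
#' @param records sorted variant records.
#' @param window_size window width in bases.
#' @return data.frame with columns `chrom, window_index, start, end,
#'   n_sites, mean_tumor_cov, mean_normal_cov, ratio` (raw, un-normalized
#'   tumor/normal coverage ratio; `NA` where normal coverage is 0).
#' @export
build_windows <- function(records, window_size = 100L) {
  validate_records(records)
  ws <- as.integer(window_size)
  if (nrow(records) == 0L)
    return(data.frame(chrom = character(), window_index = integer(),
                      start = numeric(), end = numeric(), n_sites = integer(),
                      mean_tumor_cov = numeric(), mean_normal_cov = numeric(),
                      ratio = numeric()))
  chrom <- norm_chrom(records$chrom)
  widx <- (records$pos - 1L) %/% ws
  key <- paste(chrom, widx, sep = "\r")
  agg <- rowsum(cbind(t = records$tumor_total,
                      n = records$normal_total,
                      k = 1), key, reorder = FALSE)
  first <- !duplicated(key)
  kmap <- match(rownames(agg), key[first])
  w <- data.frame(chrom = chrom[first][kmap],
                  window_index = widx[first][kmap],
                  stringsAsFactors = FALSE)
  w$start <- w$window_index * as.numeric(ws) + 1
  w$end <- (w$window_index + 1) * as.numeric(ws)
  w$n_sites <- as.integer(agg[, "k"])
  w$mean_tumor_cov <- agg[, "t"] / agg[, "k"]
  w$mean_normal_cov <- agg[, "n"] / agg[, "k"]
  w$ratio <- ifelse(w$mean_normal_cov > 0,
                    w$mean_tumor_cov / w$mean_normal_cov, NA_real_)
  w <- w[order(chrom_rank(w$chrom), w$window_index), , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Infer the diploid coverage baseline
#'
#' The coverage-ratio level treated as copy number 2.  With a user-specified
#' `diploid_region` the baseline is the median raw ratio over the windows in
#' that region.  Otherwise a provisional segmentation of the raw log2 ratios
#' is run and, among segments spanning at least `min_span` bases, the
#' coverage-ratio mode whose overlapping heterozygous sites show the
#' smallest median site-level LOH is chosen (balanced BAF implies two
#' retained haplotypes, hence diploid); ties go to the mode covering the
#' most bases.  When no segment reaches `min_span` the genome-wide median
#' ratio is used as a fallback.
#'
#' Note the documented failure mode: in a genome-wide duplicated sample the
#' duplicated state is the balanced-BAF mode, so automatic inference locks
#' onto it; specify `diploid_region` on a known-diploid region to correct.
#'
#' @param windows output of [build_windows()].
#' @param hetsites output of [call_heterozygous()].
#' @param config a [cna_config()].
#' @param min_span minimum segment span (bases) for baseline candidates.
#' @return list with `baseline` (positive scalar), `region` (description),
#'   and `method` (`"user"`, `"auto"` or `"fallback"`).
#' @export
infer_diploid_baseline <- function(windows, hetsites, config = cna_config(),
                                   min_span = 5e6) {
  if (nrow(windows) == 0L) stop("no coverage windows")
  ok <- !is.na(windows$ratio) & windows$ratio > 0
  w <- windows[ok, , drop = FALSE]
  if (nrow(w) == 0L) stop("no windows with positive coverage ratio")

  if (!is.null(config$diploid_region)) {
    reg <- parse_region(config$diploid_region)
    inreg <- w$chrom == reg$chrom & w$start >= reg$start & w$end <= reg$end
    if (!any(inreg))
      stop("specified diploid region '", config$diploid_region,
           "' contains no coverage windows")
    return(list(baseline = stats::median(w$ratio[inreg]),
                region = as.character(config$diploid_region),
                method = "user"))
  }

  # Provisional segmentation on log2(ratio / genome-wide median).
  gmed <- stats::median(w$ratio)
  w$log2_ratio <- log2(pmax(w$ratio, gmed * 2^-8) / gmed)
  segs <- merge_adjacent(
    recursive_partition(w, min_windows = config$min_windows,
                        min_gain = config$min_gain),
    merge_tol = config$merge_tol)
  segs$span <- segs$end - segs$start + 1
  cand <- segs[segs$span >= min_span, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(baseline = gmed,
                region = "genome-wide median (no segment reached min_span)",
                method = "fallback"))
  }

  # Median raw ratio and pooled het-site LOH per candidate segment.
  cand$med_ratio <- NA_real_
  seg_loh <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    inw <- w$chrom == cand$chrom[i] & w$start >= cand$start[i] &
      w$end <= cand$end[i]
    cand$med_ratio[i] <- stats::median(w$ratio[inw])
    if (nrow(hetsites)) {
      inh <- hetsites$chrom == cand$chrom[i] & hetsites$pos >= cand$start[i] &
        hetsites$pos <= cand$end[i]
      seg_loh[[i]] <- hetsites$site_loh[inh]
    } else seg_loh[[i]] <- numeric(0)
  }

  # Group candidate segments into coverage-ratio modes (gap > 0.1 in log2
  # starts a new mode), then score each mode by its pooled median site LOH.
  o <- order(cand$med_ratio)
  lr <- log2(cand$med_ratio[o])
  grp <- cumsum(c(1, diff(lr) > 0.1))
  modes <- lapply(split(o, grp), function(ix) {
    loh <- unlist(seg_loh[ix])
    list(ix = ix,
         med_loh = if (length(loh) >= 10) stats::median(loh) else Inf,
         span = sum(cand$span[ix]))
  })
  score <- vapply(modes, function(m) m$med_loh, 0)
  span <- vapply(modes, function(m) m$span, 0)
  best <- which(score <= min(score) + 1e-9)
  best <- best[which.max(span[best])]
  ix <- modes[[best]]$ix
  inw <- rep(FALSE, nrow(w))
  for (i in ix)
    inw <- inw | (w$chrom == cand$chrom[i] & w$start >= cand$start[i] &
                    w$end <= cand$end[i])
  list(baseline = stats::median(w$ratio[inw]),
       region = paste0(
         paste(sprintf("%s:%d-%d", cand$chrom[ix], cand$start[ix],
                       cand$end[ix]), collapse = ","),
         " (balanced-BAF mode)"),
       method = "auto")
}

#' Normalize window coverage ratios against the diploid baseline
#'
#' Sets `ratio = (mean_tumor_cov / mean_normal_cov) / baseline` so that
#' diploid windows sit at ratio 1, and `log2_ratio = log2(ratio)` (ratios
#' are floored at 2^-8 before the log to keep homozygous-deletion windows
#' finite).  Windows with zero normal coverage are removed.
#'
#' @param windows output of [build_windows()].
#' @param baseline_ratio positive scalar from [infer_diploid_baseline()].
#' @return windows with updated `ratio` and a `log2_ratio` column.
#' @export
normalize_ratios <- function(windows, baseline_ratio) {
  stopifnot(is.numeric(baseline_ratio), baseline_ratio > 0)
  keep <- windows$mean_normal_cov > 0
  w <- windows[keep, , drop = FALSE]
  w$ratio <- (w$mean_tumor_cov / w$mean_normal_cov) / baseline_ratio
  w$log2_ratio <- log2(pmax(w$ratio, 2^-8))
  rownames(w) <- NULL
  w
}
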