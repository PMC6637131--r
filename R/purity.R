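# Tumor purity estimation from segment-level measured CNA (x) and
# LOH / allelic-imbalance signals at germline-heterozygous sites.
#
# Model: in a segment let x be the fraction of cells carrying a single-copy
# gain (x > 0) or loss (x < 0) and y the fraction with copy-neutral LOH
# aligned with it.  The two tumor BAF clusters of a CNA of size `cna` sit at
# (1 + cna)/(2 + cna) and 1/(2 + cna); their separation is 2 * LOH.  The
# combined measured LOH is (2 y + |x|)/(4 + 2 x), hence
# y = LOH (2 + x) - |x|/2 and purity = |x| + y = LOH (2 + x) + |x|/2.

#' @importFrom mclust Mclust mclustBIC
NULL

#' B-allele frequency
#'
#' @param mutant alt-supporting read count(s).
#' @param total read depth(s); must be positive.
#' @return `mutant / total`.
#' @examples baf(30, 60)
#' @export
baf <- function(mutant, total) {
  if (any(total == 0)) stop("no coverage: total read depth is 0")
  mutant / total
}

#' Site-level LOH (allelic imbalance)
#'
#' Absolute difference between tumor and germline BAF at a heterozygous
#' site; symmetric in its arguments.
#'
#' @param baf_tumor,baf_normal fractions in \[0, 1\].
#' @return `|baf_tumor - baf_normal|`.
#' @export
site_loh <- function(baf_tumor, baf_normal) abs(baf_tumor - baf_normal)

#' Expected BAF cluster centers for a measured CNA
#'
#' For a CNA of signed cell fraction `cna` the two heterozygous-site BAF
#' clusters are expected at `(1 + cna)/(2 + cna)` and `1/(2 + cna)`; their
#' separation `|cna/(2 + cna)|` equals twice the segment LOH.  The
#' "left"/"right" labels carry no positional meaning for gains.
#'
#' @param cna measured CNA fraction, must exceed -2.
#' @return list with `left`, `right` and `distance`.
#' @examples baf_cluster_centers(-1)
#' @export
baf_cluster_centers <- function(cna) {
  if (any(cna <= -2)) stop("cna must be > -2")
  list(left = (1 + cna) / (2 + cna),
       right = 1 / (2 + cna),
       distance = abs(cna / (2 + cna)))
}

#' Segment-level LOH from tumor BAFs
#'
#' Estimates half the separation of the two tumor BAF clusters of a
#' segment.  The BAFs are split into two populations by a deterministic
#' 2-center k-means (centers initialized at the 25%/75% quantiles) and the
#' LOH is half the distance between the cluster centers, capped at 0.5.
#' When the BAF distribution is (numerically) unimodal the median folded
#' deviation `|baf - 0.5|` is used instead.  Segments with fewer than
#' `min_sites` heterozygous sites are excluded (returns `NA`).
#'
#' @param baf_tumor tumor BAFs of the heterozygous sites on one segment.
#' @param min_sites minimum site count (default 10).
#' @return LOH in \[0, 0.5\], or `NA` when the segment is excluded.
#' @examples segment_loh(rep(c(0.25, 0.75), 10))
#' @export
segment_loh <- function(baf_tumor, min_sites = 10L) {
  b <- baf_tumor[!is.na(baf_tumor)]
  if (length(b) < min_sites) return(NA_real_)
  q <- stats::quantile(b, c(0.25, 0.75), names = FALSE)
  if (diff(q) < 1e-8) {
    # unimodal (or degenerate) distribution: median folded deviation
    return(min(stats::median(abs(b - 0.5)), 0.5))
  }
  km <- stats::kmeans(b, centers = matrix(q, ncol = 1))
  ctr <- sort(km$centers[, 1L])
  min((ctr[2L] - ctr[1L]) / 2, 0.5)
}

#' Combined measured LOH for cell fractions (x, y)
#'
#' The LOH expected in a segment where a fraction `x` of cells carries a
#' single-copy CNA and a fraction `y` carries aligned copy-neutral LOH:
#' `(2 y + |x|)/(4 + 2 x)`.
#'
#' @param x signed single-copy CNA cell fraction in \[-1, 1\].
#' @param y copy-neutral LOH cell fraction.
#' @return expected LOH.
#' @export
combined_loh <- function(x, y) (2 * y + abs(x)) / (4 + 2 * x)

#' Copy-neutral LOH cell fraction from measured (x, LOH)
#'
#' Inverts [combined_loh()]: `y = LOH (2 + x) - 0.5 |x|`.  Slightly
#' negative values (within `tol`) are clamped to 0; values below `-tol`
#' are model-inconsistent and flagged in the `"inconsistent"` attribute.
#'
#' @param x signed single-copy CNA cell fraction in \[-1, 1\].
#' @param loh measured segment LOH in \[0, 0.5\].
#' @param tol negativity tolerance before flagging.
#' @return `y`, clamped at 0, with a logical `"inconsistent"` attribute.
#' @export
cn_loh_fraction <- function(x, loh, tol = 0.02) {
  y_raw <- loh * (2 + x) - 0.5 * abs(x)
  y <- pmax(y_raw, 0)
  attr(y, "inconsistent") <- y_raw < -tol
  y
}

#' Per-segment tumor purity
#'
#' `purity = |x| + y = LOH (2 + x) + |x|/2`, clamped to \[0, 1\].
#'
#' @param x signed single-copy CNA cell fraction; requires `|x| <= 1`
#'   (segments beyond a clonal single-copy event are ineligible and should
#'   have been filtered by [eligible_segments()]).
#' @param loh measured segment LOH in \[0, 0.5\].
#' @return purity fraction in \[0, 1\].
#' @examples segment_purity(-0.5, 1/6)
#' @export
segment_purity <- function(x, loh) {
  if (any(abs(x) > 1 + 1e-9))
    stop("|x| > 1: segment outside the single-copy range; filter with eligible_segments()")
  clamp01(loh * (2 + x) + abs(x) / 2)
}

#' Select segments eligible for purity estimation
#'
#' Purity is estimated only from copy-neutral and single-copy gain/loss
#' segments: `-1 <= x <= 1` with at least `min_het_sites` heterozygous
#' sites.  High-level amplifications, deep deletions and sex chromosomes
#' (the het-site model assumes two germline haplotypes) are excluded.
#'
#' @param segments classified segments carrying `x` and `n_het_sites`.
#' @param min_het_sites minimum heterozygous sites per segment.
#' @return the eligible subset.
#' @export
eligible_segments <- function(segments, min_het_sites = 10L) {
  keep <- abs(segments$x) <= 1 + 1e-9 &
    !(norm_chrom(segments$chrom) %in% c("X", "Y", "MT")) &
    !is.na(segments$n_het_sites) & segments$n_het_sites >= min_het_sites
  segments[keep, , drop = FALSE]
}

#' Sample-level tumor purity from per-segment estimates
#'
#' Fits one-dimensional Gaussian mixtures with 1..5 components to the
#' per-segment purity estimates, selects the model by BIC (via
#' \pkg{mclust}), and reports the highest cluster center as the sample
#' purity, clamped to \[0, 1\].  Fewer than `min_segments` estimates
#' (default 20) yields `reliable = FALSE` and an undefined purity.
#'
#' @param estimates numeric vector of per-segment purity estimates, or a
#'   data.frame with a `purity` column.
#' @param min_segments minimum number of estimates for a reliable call.
#' @return an object of class `"purity_result"`: list with `purity`,
#'   `reliable`, `cluster_centers`, `n_estimates`, `estimates`.
#' @export
estimate_sample_purity <- function(estimates, min_segments = 20L) {
  tab <- NULL
  if (is.data.frame(estimates)) {
    tab <- estimates
    estimates <- estimates$purity
  }
  v <- estimates[!is.na(estimates)]
  res <- list(purity = NA_real_, reliable = FALSE,
              cluster_centers = numeric(0), n_estimates = length(v),
              estimates = if (is.null(tab)) v else tab)
  class(res) <- "purity_result"
  if (length(v) < min_segments) return(res)

  centers <- if (stats::sd(v) < 1e-8) {
    mean(v)
  } else {
    fit <- tryCatch(
      mclust::Mclust(v, G = 1:min(5L, length(v) - 1L), verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      # quantile-seeded k-means scored by BIC, used only if mclust fails
      best <- NULL; best_bic <- -Inf
      for (k in 1:min(5L, length(unique(v)))) {
        ctr <- unique(stats::quantile(v, probs = seq(0.5 / k, 1 - 0.5 / k,
                                                     length.out = k),
                                      names = FALSE))
        km <- if (length(ctr) < 2L) {
          list(centers = matrix(mean(v)),
               tot.withinss = sum((v - mean(v))^2))
        } else {
          suppressWarnings(stats::kmeans(v, centers = matrix(ctr, ncol = 1)))
        }
        sig2 <- max(km$tot.withinss / length(v), 1e-12)
        bic <- -length(v) * log(sig2) - 2 * k * log(length(v))
        if (bic > best_bic) { best_bic <- bic; best <- km$centers[, 1L] }
      }
      best
    } else fit$parameters$mean
  }
  res$cluster_centers <- sort(unname(centers))
  res$purity <- clamp01(max(res$cluster_centers))
  res$reliable <- TRUE
  res
}

#' @export
print.purity_result <- function(x, ...) {
  cat("<purity_result>\n")
  cat("  per-segment estimates:", x$n_estimates, "\n")
  if (x$reliable) {
    cat("  cluster centers:",
        paste(sprintf("%.3f", x$cluster_centers), collapse = ", "), "\n")
    cat(sprintf("  tumor purity: %.3f\n", x$purity))
  } else {
    cat("  tumor purity: undefined (fewer than the required",
        "number of segment estimates)\n")
  }
  invisible(x)
}

#' Per-segment purity table for a segmented profile
#'
#' Assigns heterozygous sites to segments by position, computes each
#' eligible segment's LOH ([segment_loh()]), CN-LOH fraction
#' ([cn_loh_fraction()]) and purity ([segment_purity()]), and summarizes
#' them with [estimate_sample_purity()].
#'
#' @param segments classified segments (from [classify_cna()]).
#' @param hetsites heterozygous-site table (from [call_heterozygous()]).
#' @param config a [cna_config()].
#' @return list with `table` (per-segment data.frame: `chrom, start, end,
#'   x, loh, y, purity, n_het_sites`) and `result` (a `"purity_result"`).
#' @export
purity_profile <- function(segments, hetsites, config = cna_config()) {
  segments$segment_id <- seq_len(nrow(segments))
  hs <- assign_sites_to_segments(hetsites, segments)
  nh <- table(factor(hs$segment_id, levels = segments$segment_id))
  segments$n_het_sites <- as.integer(nh)
  elig <- eligible_segments(segments, min_het_sites = config$min_het_sites)
  if (nrow(elig) == 0L) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), x = numeric(), loh = numeric(),
                        y = numeric(), purity = numeric(),
                        n_het_sites = integer())
    return(list(table = empty,
                result = estimate_sample_purity(numeric(0),
                                                config$min_purity_segments),
                segments = segments))
  }
  elig$loh <- vapply(elig$segment_id, function(id)
    segment_loh(hs$baf_tumor[hs$segment_id == id],
                min_sites = config$min_het_sites), 0)
  elig$y <- as.numeric(cn_loh_fraction(elig$x, elig$loh))
  elig$purity <- segment_purity(elig$x, elig$loh)
  tab <- elig[, c("chrom", "start", "end", "x", "loh", "y", "purity",
                  "n_het_sites")]
  rownames(tab) <- NULL
  list(table = tab,
       result = estimate_sample_purity(tab, config$min_purity_segments),
       segments = segments)
}

# Map het sites onto segments by position; adds a segment_id column
# (NA when a site falls outside every segment).
assign_sites_to_segments <- function(hetsites, segments) {
  hetsites$segment_id <- NA_integer_
  if (!nrow(hetsites) || !nrow(segments)) return(hetsites)
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    hix <- which(hetsites$chrom == ch)
    if (!length(hix)) next
    idx <- findInterval(hetsites$pos[hix], seg$start)
    ok <- idx >= 1L & hetsites$pos[hix] <= seg$end[pmax(idx, 1L)]
    hetsites$segment_id[hix[ok]] <- seg$segment_id[idx[ok]]
  }
  hetsites
}
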