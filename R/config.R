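#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the CNA-calling pipeline.  The
#' coverage-range scale factors mirror the tool's command-line options:
#' the minimum (maximum) acceptable normal-sample depth is the median
#' normal coverage multiplied by `min_factor` (`max_factor`); on chrX the
#' `xmin_factor`/`xmax_factor` pair is used instead.
#'
#' @param sample_order which of the two genotype columns in a VCF is the
#'   tumor: `"tumor_normal"` (tumor first, the default) or `"normal_tumor"`.
#' @param diploid_region optional chromosome (`"chr21"`) or region
#'   (`"chr21:1-5000000"`) forced to be the diploid reference; when `NULL`
#'   the baseline is inferred automatically.
#' @param median_normal_coverage optional positive number; when `NULL` the
#'   median of `normal_total` over all usable records is used.
#' @param min_factor,max_factor coverage-range scale factors for autosomes
#'   (bounds are inclusive).
#' @param xmin_factor,xmax_factor coverage-range scale factors for chrX.
#' @param window_size coverage window width in bases (fixed at 100 bp by
#'   the method; exposed for experimentation).
#' @param blacklist_path optional BED file (0-based half-open) of suspicious
#'   SNP positions to drop before any other filtering.
#' @param het_baf_min,het_baf_max normal-sample BAF interval (inclusive)
#'   defining a germline-heterozygous site.
#' @param het_min_depth minimum normal depth for a heterozygous call.
#' @param min_windows smallest number of windows a segment may contain.
#' @param min_gain minimum split quality for the recursive partitioning:
#'   a split is accepted only if it reduces the sum of squared errors by at
#'   least `min_gain` times the chromosome's total SSE (regression-tree
#'   complexity-parameter semantics).
#' @param merge_tol adjacent segments whose mean log2 ratios differ by less
#'   than this (log2 units) are merged.
#' @param call_tol segments with `|seg_mean| >= call_tol` (seg.mean units)
#'   are called gain/loss; default 0.1, half of a 20%-purity single-copy event.
#' @param min_het_sites minimum heterozygous sites for a segment to enter
#'   purity estimation.
#' @param min_purity_segments minimum number of per-segment purity estimates
#'   required before a sample-level purity is reported (default 20).
#' @param seed integer seed for stochastic steps.
#' @return an object of class `"cna_config"` (a validated list).
#' @examples
#' cfg <- cna_config(diploid_region = "chr21")
#' cfg$min_factor
#' @export
cna_config <- function(sample_order = c("tumor_normal", "normal_tumor"),
                       diploid_region = NULL,
                       median_normal_coverage = NULL,
                       min_factor = 0.2, max_factor = 3.0,
                       xmin_factor = 0.1, xmax_factor = 3.0,
                       window_size = 100L,
                       blacklist_path = NULL,
                       het_baf_min = 0.30, het_baf_max = 0.70,
                       het_min_depth = 10L,
                       min_windows = 5L, min_gain = 1e-3,
                       merge_tol = 0.1, call_tol = 0.1,
                       min_het_sites = 10L, min_purity_segments = 20L,
                       seed = 1L) {
  sample_order <- match.arg(sample_order)
  cfg <- list(sample_order = sample_order,
              diploid_region = diploid_region,
              median_normal_coverage = median_normal_coverage,
              min_factor = min_factor, max_factor = max_factor,
              xmin_factor = xmin_factor, xmax_factor = xmax_factor,
              window_size = as.integer(window_size),
              blacklist_path = blacklist_path,
              het_baf_min = het_baf_min, het_baf_max = het_baf_max,
              het_min_depth = as.integer(het_min_depth),
              min_windows = as.integer(min_windows), min_gain = min_gain,
              merge_tol = merge_tol, call_tol = call_tol,
              min_het_sites = as.integer(min_het_sites),
              min_purity_segments = as.integer(min_purity_segments),
              seed = as.integer(seed))
  if (!is.null(cfg$median_normal_coverage) && cfg$median_normal_coverage <= 0)
    stop("median_normal_coverage must be positive")
  if (cfg$min_factor >= cfg$max_factor)
    stop("min_factor must be < max_factor")
  if (cfg$xmin_factor >= cfg$xmax_factor)
    stop("xmin_factor must be < xmax_factor")
  if (cfg$min_factor <= 0 || cfg$xmin_factor <= 0)
    stop("scale factors must be positive")
  if (cfg$window_size < 1L) stop("window_size must be >= 1")
  if (cfg$min_windows < 2L) stop("min_windows must be >= 2")
  if (cfg$het_baf_min > cfg$het_baf_max)
    stop("het_baf_min must be <= het_baf_max")
  class(cfg) <- "cna_config"
  cfg
}

#' @export
print.cna_config <- function(x, ...) {
  cat("<cna_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "<auto>" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
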