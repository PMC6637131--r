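# Single-command pipeline: variant parsing -> preprocessing filters -> windows
# -> diploid baseline -> segmentation -> classification -> purity.

#' Call somatic CNAs (and tumor purity) from a paired variant file
#'
#' Runs the full pipeline: [snv_counts()] materialization, blacklist and
#' coverage-range filtering, heterozygous-site identification, 100-bp
#' window construction, diploid-baseline inference/normalization,
#' recursive-partitioning segmentation with adjacent-segment merging,
#' gain/loss classification, and CNA/LOH-based tumor purity estimation.
#'
#' @param x input: a variant-record data.frame, or a path to a VCF
#'   (`.vcf`/`.vcf.gz`), MAF (`.maf`), or tab-delimited allele-count table.
#' @param config a [cna_config()].
#' @param format input format; `"auto"` guesses from the file extension.
#' @return object of class `"cna_result"`: list with `segments` (classified
#'   segment table), `purity` (a `"purity_result"`), `purity_table`
#'   (per-segment estimates), `het_sites`, `windows`, `baseline`,
#'   `normal_coverage`, `config` and `log` (effective parameters and
#'   per-stage record counts).
#' @examples
#' \donttest{
#' prof <- truth_profile(
#'   c(chr1 = 12e6),
#'   data.frame(chrom = "chr1", start = 3e6, end = 5e6, cn_a = 2, cn_b = 1),
#'   purity = 1, mean_depth = 30, depth_model = "none")
#' res <- cna_call(simulate_records(prof, seed = 7)$records)
#' res$segments
#' }
#' @export
cna_call <- function(x, config = cna_config(),
                     format = c("auto", "vcf", "maf", "bambino", "records")) {
  format <- match.arg(format)
  set.seed(config$seed)
  if (is.data.frame(x)) {
    records <- x
  } else {
    if (format == "auto") {
      format <- if (grepl("\\.vcf(\\.gz)?$", x, ignore.case = TRUE)) "vcf"
      else if (grepl("\\.maf(\\.gz)?$", x, ignore.case = TRUE)) "maf"
      else "bambino"
    }
    records <- switch(format,
                      vcf = read_paired_vcf(x, config$sample_order),
                      maf = read_maf(x),
                      bambino = read_bambino(x),
                      records = stop("format 'records' requires a data.frame"))
  }
  log <- list(parameters = unclass(config), n_input = nrow(records))

  sc <- snv_counts(records)
  records <- sc$records
  if (!is.null(config$blacklist_path))
    records <- apply_blacklist(records, config$blacklist_path)
  records <- drop_nonmodel_chroms(records)
  log$n_after_blacklist <- nrow(records)

  med <- config$median_normal_coverage
  if (is.null(med)) med <- unname(sc$normal_coverage["median"])
  records <- coverage_filter(records, config, median_normal_coverage = med)
  log$median_normal_coverage <- med
  log$n_after_coverage_filter <- nrow(records)
  if (nrow(records) == 0L) stop("no usable variants after filtering")

  hets <- call_heterozygous(records, config)
  log$n_het_sites <- nrow(hets)

  windows <- build_windows(records, config$window_size)
  log$n_windows <- nrow(windows)

  bl <- infer_diploid_baseline(windows, hets, config)
  log$baseline <- bl
  windows <- normalize_ratios(windows, bl$baseline)

  leaves <- recursive_partition(windows, min_windows = config$min_windows,
                                min_gain = config$min_gain)
  log$n_segments_pre_merge <- nrow(leaves)
  segments <- merge_adjacent(leaves, merge_tol = config$merge_tol)
  segments <- classify_cna(segments, call_tol = config$call_tol)
  log$n_segments <- nrow(segments)

  pp <- purity_profile(segments, hets, config)

  structure(list(segments = pp$segments, purity = pp$result,
                 purity_table = pp$table, het_sites = hets,
                 windows = windows, baseline = bl,
                 normal_coverage = sc$normal_coverage,
                 pre_merge_segments = leaves,
                 config = config, log = log),
            class = "cna_result")
}

#' @export
print.cna_result <- function(x, ...) {
  s <- x$segments
  cat("<cna_result>\n")
  cat(sprintf("  %d segment(s) on %d chromosome(s): %d gain, %d loss, %d neutral\n",
              nrow(s), length(unique(s$chrom)),
              sum(s$cna_class == "gain"), sum(s$cna_class == "loss"),
              sum(s$cna_class == "neutral")))
  cat(sprintf("  diploid baseline %.4f [%s: %s]\n", x$baseline$baseline,
              x$baseline$method, x$baseline$region))
  if (x$purity$reliable)
    cat(sprintf("  tumor purity %.3f (%d segment estimates)\n",
                x$purity$purity, x$purity$n_estimates))
  else
    cat(sprintf("  tumor purity undefined (%d segment estimates, %d required)\n",
                x$purity$n_estimates, x$config$min_purity_segments))
  invisible(x)
}

#' Write the outputs of a pipeline run
#'
#' Writes the CNA segment table (`<prefix>.cna.txt`, see
#' [write_cna_table()]), an IGV-compatible `.seg` export, a JSON purity
#' report (per-segment table, cluster centers, final purity, reliability,
#' diploid region used), and a JSON run log with all effective parameters.
#'
#' @param result a `"cna_result"` from [cna_call()].
#' @param prefix output path prefix.
#' @return (invisibly) named list of the written paths.
#' @export
write_cna_result <- function(result, prefix) {
  stopifnot(inherits(result, "cna_result"))
  paths <- list(cna = paste0(prefix, ".cna.txt"),
                seg = paste0(prefix, ".igv.seg"),
                purity = paste0(prefix, ".purity.json"),
                log = paste0(prefix, ".runlog.json"))
  write_cna_table(result$segments, paths$cna)
  write_igv_seg(result$segments, paths$seg, sample_id = basename(prefix))
  pr <- result$purity
  jsonlite::write_json(
    list(purity = pr$purity, reliable = pr$reliable,
         cluster_centers = pr$cluster_centers,
         n_segment_estimates = pr$n_estimates,
         diploid_region = result$baseline$region,
         segments = result$purity_table),
    paths$purity, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  jsonlite::write_json(result$log, paths$log, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(paths)
}
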