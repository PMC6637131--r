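# Step 1 of the pipeline: parse paired tumor-normal variant files into
# per-site allele-count records and summarize normal coverage.

#' Read a paired tumor-normal VCF
#'
#' Parses a VCF 4.x file with exactly two genotype columns and returns one
#' record per bi-allelic SNV carrying the four allele counts (tumor mutant /
#' total, normal mutant / total).  Counts are taken from the per-sample `AD`
#' FORMAT field (`total = sum(AD)`, `mutant = AD[2]`); rows without a
#' parseable AD, indels and multi-allelic rows are skipped and counted in a
#' message.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_order `"tumor_normal"` if the first genotype column after
#'   FORMAT is the tumor, `"normal_tumor"` for the reverse.
#' @return data.frame with columns `chrom, pos, ref, alt, tumor_mutant,
#'   tumor_total, normal_mutant, normal_total`, one row per usable site.
#' @seealso [read_bambino()], [read_maf()], [snv_counts()]
#' @export
read_paired_vcf <- function(path, sample_order = c("tumor_normal", "normal_tumor")) {
  sample_order <- match.arg(sample_order)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) != 3L)
    stop("VCF must carry exactly two genotype columns after FORMAT (found ",
         max(0L, ncol(v@gt) - 1L), ")")
  fix <- v@fix
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])

  snv <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip_shape <- sum(!snv)

  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("no genotype row carries an AD (allele depth) field")

  parse_ad <- function(x) {
    # "ref,alt" -> c(mutant, total); NA when unparseable
    out <- matrix(NA_integer_, nrow = length(x), ncol = 2L)
    ok <- !is.na(x) & grepl(",", x, fixed = TRUE)
    if (any(ok)) {
      sp <- strsplit(x[ok], ",", fixed = TRUE)
      two <- vapply(sp, function(p) suppressWarnings(
        as.integer(p[seq_len(2L)])), integer(2L))
      out[ok, 1L] <- two[2L, ]               # alt-supporting reads
      out[ok, 2L] <- two[1L, ] + two[2L, ]   # total = ref + alt
    }
    out
  }
  ad1 <- parse_ad(ad[, 1L])
  ad2 <- parse_ad(ad[, 2L])

  if (sample_order == "tumor_normal") {
    tum <- ad1; nor <- ad2
  } else {
    tum <- ad2; nor <- ad1
  }

  usable <- snv & !is.na(tum[, 1L]) & !is.na(nor[, 1L])
  n_skip_ad <- sum(snv & !usable)
  if (n_skip_shape + n_skip_ad > 0L)
    message("read_paired_vcf: skipped ", n_skip_shape,
            " indel/multi-allelic row(s) and ", n_skip_ad,
            " row(s) without parseable AD")
  if (!any(usable)) stop("no usable bi-allelic SNV rows with allele depths")

  new_records(chrom[usable], pos[usable], ref[usable], alt[usable],
              tum[usable, 1L], tum[usable, 2L],
              nor[usable, 1L], nor[usable, 2L])
}

#' Read a tab-delimited allele-count variant table
#'
#' Reads the package's Bambino-style flat format: eight tab-separated
#' columns `chrom, pos, ref, alt, tumor_mutant, tumor_total, normal_mutant,
#' normal_total`, with or without a header line.  Rows with negative or
#' inconsistent counts are rejected with a message.
#'
#' @param path file path.
#' @return variant-record data.frame (see [read_paired_vcf()]).
#' @export
read_bambino <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty variant table: ", path)
    return(new_records(character(), integer(), character(), character(),
                       integer(), integer(), integer(), integer()))
  }
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 8L)
      stop("headerless variant table needs 8 columns, found ", ncol(df))
    names(df)[1:8] <- .record_cols
  }
  missing <- setdiff(.record_cols, names(df))
  if (length(missing))
    stop("variant table missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("variant table has a header but no rows: ", path)
    return(new_records(character(), integer(), character(), character(),
                       integer(), integer(), integer(), integer()))
  }
  cnt <- df[, c("tumor_mutant", "tumor_total", "normal_mutant", "normal_total")]
  bad <- apply(cnt, 1L, function(r) anyNA(r) || any(r < 0)) |
    cnt$tumor_mutant > cnt$tumor_total |
    cnt$normal_mutant > cnt$normal_total
  if (any(bad))
    message("read_bambino: rejected ", sum(bad),
            " row(s) with negative/inconsistent counts")
  df <- df[!bad, , drop = FALSE]
  new_records(df$chrom, df$pos, df$ref, df$alt,
              df$tumor_mutant, df$tumor_total,
              df$normal_mutant, df$normal_total)
}

#' Write records in the tab-delimited allele-count format
#'
#' Counterpart of [read_bambino()]; a written table re-read compares equal.
#'
#' @param records variant-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bambino <- function(records, path) {
  validate_records(records)
  utils::write.table(records[, .record_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF (Mutation Annotation Format) file
#'
#' Extracts tumor/normal ref and alt read counts from the standard MAF
#' columns (`t_alt_count`, `t_ref_count`, `n_alt_count`, `n_ref_count`);
#' totals are `ref + alt`.  Non-SNP rows and rows with missing counts are
#' skipped with a message.
#'
#' @param path MAF file path.
#' @return variant-record data.frame (see [read_paired_vcf()]).
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- cands[tolower(cands) %in% tolower(names(df))]
    if (!length(hit))
      stop("MAF missing required column: ", cands[1])
    names(df)[match(tolower(hit[1]), tolower(names(df)))]
  }
  if (nrow(df) == 0L)
    return(new_records(character(), integer(), character(), character(),
                       integer(), integer(), integer(), integer()))
  chrom <- df[[pick("Chromosome")]]
  pos <- df[[pick(c("Start_Position", "Start_position"))]]
  ref <- df[[pick("Reference_Allele")]]
  alt <- df[[pick(c("Tumor_Seq_Allele2", "Tumor_Seq_Allele1"))]]
  ta <- df[[pick("t_alt_count")]]; tr <- df[[pick("t_ref_count")]]
  na_ <- df[[pick("n_alt_count")]]; nr <- df[[pick("n_ref_count")]]
  snv <- !is.na(ref) & !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  cnt_ok <- !(is.na(ta) | is.na(tr) | is.na(na_) | is.na(nr))
  keep <- snv & cnt_ok
  if (any(!keep))
    message("read_maf: skipped ", sum(!keep),
            " non-SNP row(s) or row(s) with missing counts")
  new_records(chrom[keep], pos[keep], ref[keep], alt[keep],
              ta[keep], ta[keep] + tr[keep],
              na_[keep], na_[keep] + nr[keep])
}

#' Materialize, sort and summarize variant records
#'
#' Sorts records in karyotype order (1..22, X, Y, MT, then others
#' lexicographically) by position, drops duplicate (chrom, pos) entries,
#' and computes the mean and median normal-sample depth used downstream by
#' the coverage-range filter.
#'
#' @param records variant-record data.frame.
#' @return list with elements `records` (sorted, de-duplicated) and
#'   `normal_coverage` (named vector with `mean` and `median` of
#'   `normal_total`).
#' @examples
#' r <- data.frame(chrom = "1", pos = c(3, 1, 2), ref = "A", alt = "G",
#'                 tumor_mutant = 5, tumor_total = 10,
#'                 normal_mutant = 5, normal_total = c(60, 40, 50))
#' snv_counts(r)$normal_coverage
#' @export
snv_counts <- function(records) {
  validate_records(records)
  if (nrow(records) == 0L) stop("no usable variants")
  records$chrom <- norm_chrom(records$chrom)
  o <- order(chrom_rank(records$chrom), records$pos)
  records <- records[o, , drop = FALSE]
  dup <- duplicated(records[, c("chrom", "pos")])
  if (any(dup)) {
    message("snv_counts: dropped ", sum(dup), " duplicate position(s)")
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  list(records = records,
       normal_coverage = c(mean = mean(records$normal_total),
                           median = stats::median(records$normal_total)))
}
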