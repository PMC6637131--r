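# Internal helpers shared across modules.

# Canonical karyotype order for sorting; chromosome names are stored without
# the "chr" prefix internally.
.karyotype <- c(as.character(1:22), "X", "Y", "MT")

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix and maps mitochondrial aliases to "MT" so
#' that inputs in mixed naming dialects compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector of canonical names ("1".."22", "X", "Y", "MT", ...).
#' @examples
#' norm_chrom(c("chr1", "1", "chrX", "chrM"))
#' @export
norm_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x[x %in% c("M", "m", "mt", "Mt")] <- "MT"
  x[x %in% c("x")] <- "X"
  x[x %in% c("y")] <- "Y"
  x
}

# Deterministic chromosome ordering: karyotype 1..22, X, Y, MT, then any
# other names appended lexicographically.
chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  c(.karyotype[.karyotype %in% u], sort(setdiff(u, .karyotype)))
}

chrom_rank <- function(chroms) {
  match(as.character(chroms), chrom_levels(chroms))
}

# Validate a variant-record data.frame (one bi-allelic site per row).
.record_cols <- c("chrom", "pos", "ref", "alt",
                  "tumor_mutant", "tumor_total",
                  "normal_mutant", "normal_total")

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.record_cols, names(records))
  if (length(missing))
    stop("variant records missing column(s): ", paste(missing, collapse = ", "))
  with(records, {
    if (any(pos < 1)) stop("variant positions must be >= 1")
    if (any(tumor_mutant < 0 | normal_mutant < 0 |
            tumor_mutant > tumor_total | normal_mutant > normal_total))
      stop("allele counts violate 0 <= mutant <= total")
  })
  invisible(records)
}

new_records <- function(chrom, pos, ref, alt,
                        tumor_mutant, tumor_total,
                        normal_mutant, normal_total) {
  validate_records(data.frame(
    chrom = norm_chrom(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    tumor_mutant = as.integer(tumor_mutant),
    tumor_total = as.integer(tumor_total),
    normal_mutant = as.integer(normal_mutant),
    normal_total = as.integer(normal_total),
    stringsAsFactors = FALSE))
}

# Parse a region string "chr21" or "chr21:500-1500" into a list.
parse_region <- function(x) {
  x <- as.character(x)[1]
  if (grepl(":", x, fixed = TRUE)) {
    chrom <- norm_chrom(sub(":.*$", "", x))
    span <- sub("^[^:]*:", "", x)
    parts <- strsplit(span, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts))))
      stop("cannot parse region '", x, "'; expected 'chrom' or 'chrom:start-end'")
    list(chrom = chrom, start = as.numeric(parts[1]), end = as.numeric(parts[2]))
  } else {
    list(chrom = norm_chrom(x), start = -Inf, end = Inf)
  }
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
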