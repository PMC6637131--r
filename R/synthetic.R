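# Synthetic paired tumor-normal data with known segmental copy number,
# purity, subclones and CN-LOH, so the whole pipeline is testable without
# controlled-access cohorts.  The generative model is the simplest one
# consistent with the BAF expectations of the purity model: Poisson read
# depth and Binomial allele counts around the analytic BAF centers.

#' Define a ground-truth tumor profile
#'
#' Chromosomes are abstract (name + length; no reference sequence needed).
#' Each truth segment assigns per-haplotype tumor copy numbers
#' (`cn_a`, `cn_b`) to a region, carried by a fraction `clone_frac` of
#' tumor cells; `cnloh_frac` is the fraction of all cells with aligned
#' copy-neutral LOH.  Regions not covered by any segment are diploid.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bases).
#' @param segments `NULL` (fully diploid) or a data.frame with columns
#'   `chrom, start, end, cn_a, cn_b` and optional `clone_frac` (default 1)
#'   and `cnloh_frac` (default 0).  Segments must not overlap.
#' @param purity fraction of tumor cells in the sample, in \[0, 1\].
#' @param het_density germline heterozygous sites per kb (default 0.5,
#'   typical of usable WGS SNP density).
#' @param hom_density homozygous-alt filler sites per kb (default 0.5);
#'   they inform coverage but carry no het-BAF signal.
#' @param mean_depth mean normal-sample read depth (default 30).
#' @param depth_model `"poisson"` for Poisson depths and Binomial allele
#'   counts, `"none"` for deterministic (noiseless) rounded expectations.
#' @return object of class `"truth_profile"`.
#' @export
truth_profile <- function(chrom_lengths, segments = NULL, purity = 1,
                          het_density = 0.5, hom_density = 0.5,
                          mean_depth = 30, depth_model = c("poisson", "none")) {
  depth_model <- match.arg(depth_model)
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), purity >= 0, purity <= 1,
            mean_depth > 0, het_density >= 0, hom_density >= 0)
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  if (is.null(segments)) {
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), cn_a = numeric(), cn_b = numeric(),
                           clone_frac = numeric(), cnloh_frac = numeric())
  } else {
    segments <- as.data.frame(segments)
    need <- c("chrom", "start", "end", "cn_a", "cn_b")
    missing <- setdiff(need, names(segments))
    if (length(missing))
      stop("truth segments missing column(s): ", paste(missing, collapse = ", "))
    if (is.null(segments$clone_frac)) segments$clone_frac <- 1
    if (is.null(segments$cnloh_frac)) segments$cnloh_frac <- 0
    segments$chrom <- norm_chrom(segments$chrom)
    stopifnot(all(segments$chrom %in% names(chrom_lengths)),
              all(segments$start >= 1),
              all(segments$end <= chrom_lengths[segments$chrom]),
              all(segments$cn_a >= 0), all(segments$cn_b >= 0),
              all(segments$clone_frac > 0), all(segments$clone_frac <= 1),
              all(segments$cnloh_frac >= 0))
    if (any(purity * segments$clone_frac + segments$cnloh_frac > 1 + 1e-9))
      stop("purity * clone_frac + cnloh_frac must not exceed 1")
    # overlapping truth segments are a specification error
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping truth segments on chromosome ", ch)
    }
  }
  q <- purity * segments$clone_frac
  cn <- segments$cn_a + segments$cn_b
  segments$expected_ratio <- (q * cn + (1 - q) * 2) / 2
  segments$expected_seg_mean <- segments$expected_ratio - 1
  segments$expected_x <- q * (cn - 2)
  structure(list(chrom_lengths = chrom_lengths, segments = segments,
                 purity = purity, het_density = het_density,
                 hom_density = hom_density, mean_depth = mean_depth,
                 depth_model = depth_model),
            class = "truth_profile")
}

#' @export
print.truth_profile <- function(x, ...) {
  cat("<truth_profile>", length(x$chrom_lengths), "chromosome(s),",
      nrow(x$segments), "CNA segment(s), purity", x$purity,
      "\n  depth", x$mean_depth, "x (", x$depth_model, "),",
      x$het_density, "het +", x$hom_density, "hom sites/kb\n")
  invisible(x)
}

#' Simulate paired tumor-normal variant records
#'
#' Places germline het (and homozygous-alt filler) sites uniformly at the
#' profile's densities, then draws normal depth ~ Poisson(`mean_depth`),
#' tumor depth ~ Poisson(`mean_depth` * T/2) where T is the cell-averaged
#' total copy number of the site's segment, and alt reads ~ Binomial(depth,
#' expected BAF).  The B allele is assigned to a random haplotype per site;
#' the expected tumor BAF is the cell-averaged B-copy fraction, which for
#' single-copy events equals the analytic BAF cluster centers
#' ([baf_cluster_centers()]) at the effective CNA
#' `x = purity * clone_frac * (CN - 2)`.  With `depth_model = "none"`
#' depths and counts are rounded expectations (noiseless).
#'
#' @param profile a [truth_profile()].
#' @param seed integer seed.
#' @return list with `records` (variant-record data.frame) and `sites`
#'   (per-site truth: `chrom, pos, is_het, baf_expected, expected_ratio`).
#' @export
simulate_records <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "truth_profile"))
  set.seed(as.integer(seed))
  segs <- profile$segments
  p <- profile$purity
  D <- profile$mean_depth
  noiseless <- profile$depth_model == "none"
  chroms <- names(profile$chrom_lengths)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- profile$chrom_lengths[[ch]]
    n_het <- round(L * profile$het_density / 1000)
    n_hom <- round(L * profile$hom_density / 1000)
    n <- n_het + n_hom
    if (n == 0) next
    pos <- sort(sample.int(L, n))
    is_het <- sample(rep(c(TRUE, FALSE), c(n_het, n_hom)))

    # per-site segment attributes (diploid defaults outside truth segments)
    cn_a <- rep(1, n); cn_b <- rep(1, n); q <- rep(0, n); y <- rep(0, n)
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      s <- s[order(s$start), , drop = FALSE]
      idx <- findInterval(pos, s$start)
      hit <- idx >= 1L & pos <= s$end[pmax(idx, 1L)]
      cn_a[hit] <- s$cn_a[idx[hit]]
      cn_b[hit] <- s$cn_b[idx[hit]]
      q[hit] <- p * s$clone_frac[idx[hit]]
      y[hit] <- s$cnloh_frac[idx[hit]]
    }

    # cell-averaged total copies; CN-LOH cells stay at 2 total copies
    tot <- q * (cn_a + cn_b) + (1 - q) * 2
    # B allele on a random haplotype; CN-LOH keeps/duplicates the majority
    # haplotype of the CNA (aligned direction)
    b_on_1 <- stats::runif(n) < 0.5
    cnB <- ifelse(b_on_1, cn_a, cn_b)
    kept1 <- cn_a >= cn_b
    cnB_loh <- ifelse(b_on_1 == kept1, 2, 0)
    bexp <- ifelse(is_het,
                   (q * cnB + y * cnB_loh + (1 - q - y) * 1) / tot,
                   1)

    tumor_mu <- D * tot / 2
    if (noiseless) {
      nt <- rep(round(D), n)
      tt <- round(tumor_mu)
      nm <- ifelse(is_het, round(nt * 0.5), nt)
      tm <- round(tt * bexp)
    } else {
      nt <- stats::rpois(n, D)
      tt <- stats::rpois(n, tumor_mu)
      nm <- ifelse(is_het, stats::rbinom(n, nt, 0.5), nt)
      tm <- stats::rbinom(n, tt, bexp)
    }
    refb <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    altb <- vapply(refb, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    out[[ci]] <- data.frame(chrom = ch, pos = pos, ref = refb, alt = altb,
                            tumor_mutant = as.integer(tm),
                            tumor_total = as.integer(tt),
                            normal_mutant = as.integer(nm),
                            normal_total = as.integer(nt),
                            is_het = is_het, baf_expected = bexp,
                            expected_ratio = tot / 2,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(all) <- NULL
  list(records = validate_records(all[, .record_cols]),
       sites = all[, c("chrom", "pos", "is_het", "baf_expected",
                       "expected_ratio")])
}

#' Simulate and write a paired tumor-normal VCF
#'
#' Runs [simulate_records()] and writes a two-sample VCF 4.2 (FORMAT
#' `GT:AD:DP`) plus tab-delimited truth tables (`<path>.truth_segments.txt`
#' with the expected ratio/seg.mean/x per truth segment, and
#' `<path>.truth_sites.txt` with per-site expectations).
#'
#' @param profile a [truth_profile()].
#' @param path output VCF path.
#' @param seed integer seed.
#' @param sample_order `"tumor_normal"` writes the tumor genotype column
#'   first; `"normal_tumor"` the reverse.
#' @param write_truth write the two truth tables next to the VCF?
#' @return (invisibly) list with `vcf`, `truth_segments`, `truth_sites`
#'   paths, and the simulated `records`.
#' @export
simulate_paired_vcf <- function(profile, path, seed = 1L,
                                sample_order = c("tumor_normal", "normal_tumor"),
                                write_truth = TRUE) {
  sample_order <- match.arg(sample_order)
  sim <- simulate_records(profile, seed = seed)
  r <- sim$records
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cnapair-simulator",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(profile$chrom_lengths),
                   as.integer(profile$chrom_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  gt_n <- ifelse(sim$sites$is_het, "0/1", "1/1")
  fmt <- function(gt, mut, tot)
    sprintf("%s:%d,%d:%d", gt, tot - mut, mut, tot)
  tum <- fmt(gt_n, r$tumor_mutant, r$tumor_total)
  nor <- fmt(gt_n, r$normal_mutant, r$normal_total)
  if (sample_order == "tumor_normal") {
    s1 <- tum; s2 <- nor; s_names <- c("TUMOR", "NORMAL")
  } else {
    s1 <- nor; s2 <- tum; s_names <- c("NORMAL", "TUMOR")
  }
  body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
                "GT:AD:DP", s1, s2, sep = "\t")
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", s_names), collapse = "\t")
  writeLines(c(hdr, col_line, body), path)
  paths <- list(vcf = path, records = r)
  if (write_truth) {
    paths$truth_segments <- paste0(path, ".truth_segments.txt")
    paths$truth_sites <- paste0(path, ".truth_sites.txt")
    utils::write.table(profile$segments, paths$truth_segments, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$sites, paths$truth_sites, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Inject library-artifact coverage bursts
#'
#' Emulates the uneven coverage introduced by library-construction
#' artifacts: short genomic bursts (uniform length between `burst_len[1]`
#' and `burst_len[2]`) are placed at `burst_rate` bursts per Mb, and the
#' tumor depth of every record inside a burst is multiplied by a log-normal
#' factor (`sdlog = burst_sdlog`).  Allele counts are rescaled with the
#' depth so BAFs are untouched; depths remain non-negative integers.
#'
#' @param records variant-record data.frame.
#' @param burst_rate bursts per Mb (0 leaves the records untouched).
#' @param burst_len length range in bases, default 1-10 kb.
#' @param burst_sdlog log-normal sd of the depth multiplier.
#' @param seed integer seed.
#' @param chrom_lengths optional named lengths; defaults to the maximum
#'   observed position per chromosome.
#' @return records with perturbed tumor depths.
#' @export
add_artifact_noise <- function(records, burst_rate = 2, burst_len = c(1e3, 1e4),
                               burst_sdlog = 0.5, seed = 1L,
                               chrom_lengths = NULL) {
  validate_records(records)
  if (burst_rate == 0 || nrow(records) == 0L) return(records)
  set.seed(as.integer(seed))
  chroms <- unique(records$chrom)
  for (ch in chroms) {
    ix <- which(records$chrom == ch)
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[norm_chrom(ch)]] else
      max(records$pos[ix])
    nb <- stats::rpois(1L, burst_rate * L / 1e6)
    if (nb == 0L) next
    bs <- stats::runif(nb, 1, L)
    bl <- stats::runif(nb, burst_len[1], burst_len[2])
    fac <- stats::rlnorm(nb, meanlog = 0, sdlog = burst_sdlog)
    for (b in seq_len(nb)) {
      inb <- ix[records$pos[ix] >= bs[b] & records$pos[ix] <= bs[b] + bl[b]]
      if (!length(inb)) next
      old_tot <- records$tumor_total[inb]
      old_baf <- ifelse(old_tot > 0, records$tumor_mutant[inb] / old_tot, 0)
      new_tot <- pmax(0L, as.integer(round(old_tot * fac[b])))
      records$tumor_total[inb] <- new_tot
      records$tumor_mutant[inb] <- as.integer(round(new_tot * old_baf))
    }
  }
  validate_records(records)
  records
}
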