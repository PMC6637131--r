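test_that("simulated VCF round-trips and sample_order swaps tumor/normal exactly", {
  prof <- truth_profile(c(chr1 = 1e6),
                        data.frame(chrom = "chr1", start = 2e5, end = 4e5,
                                   cn_a = 0, cn_b = 1),
                        purity = 1, mean_depth = 30)
  vcf <- tempfile(fileext = ".vcf")
  sim <- simulate_paired_vcf(prof, vcf, seed = 11, sample_order = "tumor_normal")

  tn <- suppressMessages(read_paired_vcf(vcf, "tumor_normal"))
  expect_equal(tn$tumor_mutant, sim$records$tumor_mutant)
  expect_equal(tn$tumor_total, sim$records$tumor_total)
  expect_equal(tn$normal_total, sim$records$normal_total)
  expect_equal(tn$pos, sim$records$pos)

  # reading the same file with the reversed order swaps the count pairs
  nt <- suppressMessages(read_paired_vcf(vcf, "normal_tumor"))
  expect_equal(nt$tumor_mutant, tn$normal_mutant)
  expect_equal(nt$tumor_total, tn$normal_total)
  expect_equal(nt$normal_mutant, tn$tumor_mutant)

  # a file written normal-first reads back correctly with the matching flag
  vcf2 <- tempfile(fileext = ".vcf")
  simulate_paired_vcf(prof, vcf2, seed = 11, sample_order = "normal_tumor")
  nt2 <- suppressMessages(read_paired_vcf(vcf2, "normal_tumor"))
  expect_equal(nt2, tn)
})

test_that("indel, multi-allelic and AD-less VCF rows are skipped", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T", "N", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:30,30\t0/1:25,25",
    "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:AD\t0/1:30,30\t0/1:25,25",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:AD\t0/1:30,30\t0/1:25,25",
    "chr1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1"), vcf)
  r <- suppressMessages(suppressWarnings(read_paired_vcf(vcf, "tumor_normal")))
  expect_equal(nrow(r), 1L)
  # tumor AD 30,30 -> mutant 30, total 60
  expect_equal(r$tumor_mutant, 30L)
  expect_equal(r$tumor_total, 60L)
  expect_equal(r$normal_total, 50L)
})

test_that("a VCF without two genotype columns is a fatal format error", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ONLY", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tAD\t30,30"), vcf)
  expect_error(suppressWarnings(read_paired_vcf(vcf)), "two genotype columns")
})

test_that("allele-count tables round-trip and reject malformed rows", {
  r <- rec_df("chr1", c(1000, 2000), c(30, 10), c(60, 40), c(25, 0), c(50, 45))
  path <- tempfile(fileext = ".txt")
  write_bambino(r, path)
  back <- read_bambino(path)
  expect_equal(back$pos, r$pos)
  expect_equal(back$tumor_mutant, r$tumor_mutant)
  expect_equal(back$normal_total, r$normal_total)

  # headerless positional form
  writeLines("chr1\t1000\tA\tG\t30\t60\t25\t50", path)
  expect_equal(read_bambino(path)$tumor_total, 60L)

  # negative count -> row rejected
  writeLines(c("chr1\t1000\tA\tG\t30\t60\t25\t50",
               "chr1\t2000\tA\tG\t-3\t60\t25\t50"), path)
  expect_equal(nrow(suppressMessages(read_bambino(path))), 1L)

  # missing required column is fatal and names the column
  writeLines(c("chrom\tpos\tref\talt\ttumor_mutant",
               "chr1\t1\tA\tG\t3"), path)
  expect_error(read_bambino(path), "tumor_total")

  # empty file -> empty stream with a warning
  writeLines(character(), path)
  expect_warning(empty <- read_bambino(path), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("MAF counts follow the ref+alt total convention", {
  path <- tempfile(fileext = ".maf")
  hdr <- paste("Chromosome", "Start_Position", "Reference_Allele",
               "Tumor_Seq_Allele2", "t_alt_count", "t_ref_count",
               "n_alt_count", "n_ref_count", sep = "\t")
  writeLines(c(hdr,
               "1\t5000\tA\tG\t12\t28\t20\t20",
               "1\t6000\tA\tG\tNA\t28\t20\t20"), path)
  r <- suppressMessages(read_maf(path))
  expect_equal(nrow(r), 1L)
  expect_equal(r$tumor_mutant, 12L)
  expect_equal(r$tumor_total, 40L)
  expect_equal(r$normal_total, 40L)

  writeLines(hdr, path)
  expect_equal(nrow(read_maf(path)), 0L)
})

test_that("snv_counts sorts karyotypically, de-duplicates and summarizes coverage", {
  r <- rec_df(c("chr10", "chr2", "chrX", "chr2", "chr2"),
              c(5, 9, 1, 3, 9), 10, 40, 10, c(40, 60, 55, 50, 60))
  out <- snv_counts(r)
  expect_equal(out$records$chrom, c("2", "2", "10", "X"))
  expect_equal(out$records$pos, c(3, 9, 5, 1))
  # mean/median of {40, 60, 50, 55} (duplicate chr2:9 dropped, first kept)
  expect_equal(unname(out$normal_coverage["mean"]), mean(c(40, 60, 50, 55)))
  expect_equal(unname(out$normal_coverage["median"]), stats::median(c(40, 60, 50, 55)))
  expect_false(any(duplicated(out$records[, c("chrom", "pos")])))
  expect_error(snv_counts(r[0, ]), "no usable variants")

  # three-record example: mean 50, median 50
  out3 <- snv_counts(rec_df("1", 1:3, 5, 20, 5, c(40, 50, 60)))
  expect_equal(unname(out3$normal_coverage), c(50, 50))
})
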