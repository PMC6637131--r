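# Builders and independent oracles shared across test files.

# Minimal variant-record builder.
rec_df <- function(chrom, pos, tm, tt, nm, nt, ref = "A", alt = "G") {
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             ref = ref, alt = alt,
             tumor_mutant = as.integer(tm), tumor_total = as.integer(tt),
             normal_mutant = as.integer(nm), normal_total = as.integer(nt),
             stringsAsFactors = FALSE)
}

# Window table from a vector of log2 ratios (one 100-bp window per value).
mkw <- function(vals, chrom = "1") {
  data.frame(chrom = rep(chrom, length(vals)),
             window_index = seq_along(vals) - 1L,
             start = (seq_along(vals) - 1) * 100 + 1,
             end = seq_along(vals) * 100,
             n_sites = rep(1L, length(vals)),
             mean_tumor_cov = rep(30, length(vals)),
             mean_normal_cov = rep(30, length(vals)),
             ratio = 2^vals, log2_ratio = vals,
             stringsAsFactors = FALSE)
}

# Exhaustive SSE-minimizing changepoint search (k = 1 or 2), the brute-force
# oracle for the recursive partitioning.
oracle_changepoints <- function(x, k, min_w = 5L) {
  n <- length(x); S <- c(0, cumsum(x)); S2 <- c(0, cumsum(x^2))
  sse <- function(a, b) { s <- S[b + 1] - S[a]; S2[b + 1] - S2[a] - s * s / (b - a + 1) }
  if (k == 1) {
    ks <- min_w:(n - min_w)
    tot <- vapply(ks, function(kk) sse(1, kk) + sse(kk + 1, n), 0)
    ks[which.min(tot)]
  } else if (k == 2) {
    best <- NULL; bv <- Inf
    for (k1 in min_w:(n - 2 * min_w)) {
      l <- sse(1, k1)
      ks2 <- (k1 + min_w):(n - min_w)
      tot <- l + vapply(ks2, function(kk) sse(k1 + 1, kk) + sse(kk + 1, n), 0)
      i <- which.min(tot)
      if (tot[i] < bv) { bv <- tot[i]; best <- c(k1, ks2[i]) }
    }
    best
  } else stop("oracle supports k <= 2")
}

# Brute-force per-base F1: materializes one call per base (tests only use
# toy genomes), the oracle for the interval-arithmetic implementation.
bf_per_base_f1 <- function(predicted, reference, chrom_lengths) {
  code <- c(gain = 1L, loss = 2L, neutral = 0L)
  paint <- function(profile, ch, L) {
    v <- integer(L)
    p <- profile[profile$chrom == ch & profile$cna_class != "neutral", , drop = FALSE]
    for (i in seq_len(nrow(p)))
      v[p$start[i]:p$end[i]] <- code[[p$cna_class[i]]]
    v
  }
  corr <- predN <- refN <- 0
  for (ch in names(chrom_lengths)) {
    pv <- paint(predicted, ch, chrom_lengths[[ch]])
    rv <- paint(reference, ch, chrom_lengths[[ch]])
    corr <- corr + sum(pv > 0 & pv == rv)
    predN <- predN + sum(pv > 0)
    refN <- refN + sum(rv > 0)
  }
  if (predN == 0 && refN == 0) return(NA_real_)
  p <- if (predN > 0) corr / predN else NA_real_
  r <- if (refN > 0) corr / refN else NA_real_
  if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
}

# Random toy CNA profile on one chromosome (for oracle-equivalence tests).
random_toy_profile <- function(L = 10000L, max_seg = 6L) {
  n <- sample.int(max_seg, 1L)
  cuts <- sort(sample.int(L - 1, n - 1))
  bounds <- cbind(c(1, cuts + 1), c(cuts, L))
  data.frame(chrom = "1", start = bounds[, 1], end = bounds[, 2],
             cna_class = sample(c("gain", "loss", "neutral"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Study-condition genome for purity parameter recovery: four 9-Mb
# chromosomes each carrying seven 600-kb single-copy CNA segments
# (alternating gain (2,1) and loss (0,1)) separated by 600-kb diploid
# spacers, plus a 6-Mb all-diploid chromosome for baseline inference.
# 60x depth, 0.5 het sites/kb => ~300 het sites per CNA segment.
purity_recovery_profile <- function(p, clone = 1) {
  segs <- do.call(rbind, lapply(1:4, function(ci) {
    st <- (2 * (1:7) - 1) * 6e5 + 1
    data.frame(chrom = as.character(ci), start = st, end = st + 6e5 - 1,
               cn_a = ifelse((1:7 + ci) %% 2 == 0, 2, 0), cn_b = 1,
               clone_frac = clone)
  }))
  truth_profile(stats::setNames(c(rep(9e6, 4), 6e6), c(as.character(1:4), "5")),
                segs, purity = p, mean_depth = 60)
}

# Pure-tumor noiseless genome used for the output-semantics checks: one
# 30-Mb chromosome, a 5-Mb (3,1) segment (absolute CN 4) and a 5-Mb (0,1)
# segment (absolute CN 1), diploid elsewhere.
output_semantics_profile <- function() {
  truth_profile(
    c("1" = 30e6),
    data.frame(chrom = "1", start = c(8e6, 20e6), end = c(13e6 - 1, 25e6 - 1),
               cn_a = c(3, 0), cn_b = c(1, 1)),
    purity = 1, mean_depth = 30, depth_model = "none")
}
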