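# Recursive-partitioning segmentation of windowed log2 coverage ratios,
# CNA classification against the diploid baseline, and seg-table I/O.

#' Recursive-partitioning segmentation
#'
#' Per chromosome, the ordered window sequence is split by binary recursive
#' partitioning of the `log2_ratio` values: at each node the split index
#' maximizing the reduction in the sum of squared errors (SSE) is chosen
#' (leftmost on ties), and the split is accepted while both children contain
#' at least `min_windows` windows and the SSE reduction is at least
#' `min_gain` times the chromosome's total SSE (regression-tree
#' complexity-parameter semantics).  Leaves become segments whose
#' `mean_log2` is the mean of their member windows; segments tile the
#' covered windows without overlap.
#'
#' @param windows data.frame with `chrom, start, end, log2_ratio`, sorted
#'   within chromosome.
#' @param min_windows minimum windows per segment (>= 2).
#' @param min_gain minimum relative SSE reduction to accept a split.
#' @return data.frame with columns `chrom, start, end, n_windows, mean_log2`.
#' @export
recursive_partition <- function(windows, min_windows = 5L, min_gain = 1e-3) {
  stopifnot(min_windows >= 2L)
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), mean_log2 = numeric()))
  if (!"log2_ratio" %in% names(windows))
    stop("windows must carry a log2_ratio column (run normalize_ratios first)")
  out <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(ix) {
    ix <- ix[order(windows$start[ix])]
    x <- windows$log2_ratio[ix]
    n <- length(x)
    S <- c(0, cumsum(x))
    S2 <- c(0, cumsum(x^2))
    sse <- function(a, b) {  # SSE of x[a..b], 1-based inclusive
      s <- S[b + 1L] - S[a]
      S2[b + 1L] - S2[a] - s * s / (b - a + 1L)
    }
    sse_root <- sse(1L, n)
    thr <- min_gain * sse_root
    leaves <- list()
    stack <- list(c(1L, n))
    while (length(stack)) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- node[1L]; j <- node[2L]
      m <- j - i + 1L
      split_at <- NA_integer_
      if (m >= 2L * min_windows) {
        ks <- (i + min_windows - 1L):(j - min_windows)
        nl <- ks - i + 1L
        nr <- j - ks
        sl <- S[ks + 1L] - S[i]
        sr <- (S[j + 1L] - S[i]) - sl
        # SSE reduction = node SSE - (left SSE + right SSE)
        gain <- sl * sl / nl + sr * sr / nr -
          (S[j + 1L] - S[i])^2 / m
        best <- which.max(gain)              # leftmost maximum
        if (gain[best] >= thr && gain[best] > 1e-12)
          split_at <- ks[best]
      }
      if (is.na(split_at)) {
        leaves[[length(leaves) + 1L]] <- c(i, j)
      } else {
        # push right first so the left child is processed next (deterministic,
        # leaves come out left-to-right after ordering below)
        stack[[length(stack) + 1L]] <- c(split_at + 1L, j)
        stack[[length(stack) + 1L]] <- c(i, split_at)
      }
    }
    leaves <- leaves[order(vapply(leaves, `[`, 0L, 1L))]
    data.frame(
      chrom = windows$chrom[ix[1L]],
      start = vapply(leaves, function(l) windows$start[ix[l[1L]]], 0),
      end = vapply(leaves, function(l) windows$end[ix[l[2L]]], 0),
      n_windows = vapply(leaves, function(l) l[2L] - l[1L] + 1L, 0L),
      mean_log2 = vapply(leaves, function(l)
        (S[l[2L] + 1L] - S[l[1L]]) / (l[2L] - l[1L] + 1L), 0),
      stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, out)
  segs <- segs[order(chrom_rank(segs$chrom), segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Merge adjacent segments with near-equal means
#'
#' Iteratively merges the neighboring same-chromosome segment pair whose
#' `mean_log2` values are closest, while that difference is below
#' `merge_tol`; merged means are recomputed weighted by `n_windows` and the
#' process repeats to a fixed point.  Guards against the hypersegmentation
#' ("fractured genome") induced by library-artifact coverage noise.
#'
#' @param segments output of [recursive_partition()] (ordered,
#'   non-overlapping).
#' @param merge_tol log2-units threshold below which neighbors merge.
#' @return merged segment data.frame; never has more rows than the input.
#' @export
merge_adjacent <- function(segments, merge_tol = 0.1) {
  if (nrow(segments) <= 1L) return(segments)
  s <- segments[order(chrom_rank(segments$chrom), segments$start), , drop = FALSE]
  repeat {
    n <- nrow(s)
    if (n <= 1L) break
    same <- s$chrom[-n] == s$chrom[-1L]
    d <- abs(s$mean_log2[-n] - s$mean_log2[-1L])
    d[!same] <- Inf
    i <- which.min(d)
    if (!is.finite(d[i]) || d[i] >= merge_tol) break
    nw <- s$n_windows[i] + s$n_windows[i + 1L]
    s$mean_log2[i] <- (s$n_windows[i] * s$mean_log2[i] +
                         s$n_windows[i + 1L] * s$mean_log2[i + 1L]) / nw
    s$n_windows[i] <- nw
    s$end[i] <- s$end[i + 1L]
    s <- s[-(i + 1L), , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

#' Classify segments as gain, loss or neutral
#'
#' Converts the mean log2 ratio of each segment (relative to the diploid
#' baseline) to the output scales: with `r = 2^mean_log2`,
#' `seg_mean = r - 1` (0.5 units per clonal copy: +1.0 is a two-copy gain,
#' -0.5 a one-copy loss) and `gmean = 2 r` (absolute copy-number scale,
#' diploid = 2.0).  A segment is a gain when `seg_mean >= call_tol`, a loss
#' when `seg_mean <= -call_tol`, otherwise neutral.  The measured-CNA
#' fraction `x = 2 * seg_mean` is attached for purity estimation.
#'
#' @param segments segment data.frame with `mean_log2`.
#' @param call_tol gain/loss call threshold in seg.mean units.
#' @return segments with added `seg_mean, gmean, cna_class, x` columns.
#' @export
classify_cna <- function(segments, call_tol = 0.1) {
  r <- 2^segments$mean_log2
  segments$seg_mean <- r - 1
  segments$gmean <- 2 * r
  segments$cna_class <- ifelse(segments$seg_mean >= call_tol, "gain",
                               ifelse(segments$seg_mean <= -call_tol,
                                      "loss", "neutral"))
  segments$x <- 2 * segments$seg_mean
  segments
}

#' Write a CNA segment table
#'
#' Tab-delimited with header `chrom, loc.start, loc.end, num.windows,
#' seg.mean, gmean, cna.class`, one row per segment, ordered by karyotype
#' position.  An empty segment list produces a header-only file.
#'
#' @param segments classified segments (see [classify_cna()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cna_table <- function(segments, path) {
  cols <- c(chrom = "chrom", loc.start = "start", loc.end = "end",
            num.windows = "n_windows", seg.mean = "seg_mean",
            gmean = "gmean", cna.class = "cna_class")
  out <- as.data.frame(lapply(cols, function(cc) segments[[cc]]))
  names(out) <- names(cols)
  if (nrow(out))
    out <- out[order(chrom_rank(out$chrom), out$loc.start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNA segment table written by [write_cna_table()]
#'
#' @param path seg-table path.
#' @return segment data.frame with the package's internal column names
#'   (`chrom, start, end, n_windows, seg_mean, gmean, cna_class, mean_log2, x`).
#' @export
read_cna_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "loc.start", "loc.end", "num.windows", "seg.mean",
            "gmean", "cna.class")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("seg table missing column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(chrom = norm_chrom(df$chrom), start = df$loc.start,
                    end = df$loc.end, n_windows = df$num.windows,
                    seg_mean = df$seg.mean, gmean = df$gmean,
                    cna_class = df$cna.class, stringsAsFactors = FALSE)
  out$mean_log2 <- log2(pmax(out$seg_mean + 1, 2^-8))
  out$x <- 2 * out$seg_mean
  out
}

#' Export segments as an IGV-compatible .seg file
#'
#' Columns `ID, chrom, loc.start, loc.end, num.mark, seg.mean`, with the
#' seg.mean column carrying the mean log2 ratio as IGV expects.
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @param sample_id sample identifier for the ID column.
#' @return `path`, invisibly.
#' @export
write_igv_seg <- function(segments, path, sample_id = "sample") {
  out <- data.frame(ID = sample_id, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_windows,
                    seg.mean = segments$mean_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
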