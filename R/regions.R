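#' Weighted methylation level of a genomic interval
#'
#' Level = sum(meth_count) / sum(depth) over strand-specific sites of the
#' requested context inside the 0-based half-open interval, counting only
#' sites with `depth >= min_depth`.  With no qualifying site the level is
#' missing (`NA`), never 0.
#'
#' @param calls Calls `data.frame` (may pool samples/replicates).
#' @param chrom,start,end Interval (0-based half-open).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_depth Minimum per-site depth (default 4).
#' @return List with `level`, `n_sites`, `total_depth`.
#' @export
region_level <- function(calls, chrom, start, end, context = "CG",
                         min_depth = 4) {
  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos < end &
    calls$context == context & calls$depth >= min_depth
  d <- sum(calls$depth[sel]); m <- sum(calls$meth_count[sel])
  list(level = if (d > 0) m / d else NA_real_,
       n_sites = sum(sel), total_depth = d)
}

#' Weighted levels for many intervals at once
#'
#' @param calls Calls `data.frame`.
#' @param intervals `data.frame` with `chrom, start, end` (extra columns kept).
#' @inheritParams region_level
#' @return `intervals` with added `level, n_sites, total_depth, total_meth`.
#' @export
region_levels <- function(calls, intervals, context = "CG", min_depth = 4) {
  calls <- calls[calls$context == context & calls$depth >= min_depth, ,
                 drop = FALSE]
  cgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  igr <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start + 1L,
                                                 intervals$end))
  ov <- GenomicRanges::findOverlaps(cgr, igr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  n <- nrow(intervals)
  dsum <- as.numeric(tapply(calls$depth[qi], factor(si, levels = seq_len(n)),
                            sum, default = 0))
  msum <- as.numeric(tapply(calls$meth_count[qi],
                            factor(si, levels = seq_len(n)), sum, default = 0))
  nsit <- as.numeric(tapply(qi, factor(si, levels = seq_len(n)),
                            length, default = 0))
  intervals$level <- ifelse(dsum > 0, msum / dsum, NA_real_)
  intervals$n_sites <- as.integer(nsit)
  intervals$total_depth <- as.integer(dsum)
  intervals$total_meth <- as.integer(msum)
  intervals
}

#' Metagene methylation profile (TSS to TTS with flanks)
#'
#' Each gene is laid out as 20 upstream flank bins of 100 bp, `body_bins`
#' length-normalised body bins, and 20 downstream flank bins of 100 bp, in
#' transcription orientation (minus-strand genes are mirrored).  Per-bin
#' levels pool methylated reads and depth over all genes (weighted level), and
#' the profile is smoothed with a centered 5-bin moving average whose window
#' shrinks symmetrically at the series ends.
#'
#' @param calls Calls `data.frame` (pool replicates before calling if a group
#'   profile is wanted).
#' @param genes Gene-model `data.frame`.
#' @param flank Flank width in bp (default 2000).
#' @param bin_width Flank bin width in bp (default 100).
#' @param body_bins Number of percent-of-gene body bins (default 60).
#' @param context,min_depth As in [region_level()].
#' @return Object of class `gm_metagene`: `data.frame` with `bin, zone,
#'   offset, level, smoothed, n_sites, total_depth`.
#' @export
metagene_profile <- function(calls, genes, flank = 2000, bin_width = 100,
                             body_bins = 60, context = "CG", min_depth = 4) {
  stopifnot(nrow(genes) >= 1)
  n_flank <- as.integer(flank / bin_width)
  n_bins <- 2L * n_flank + body_bins
  calls <- calls[calls$context == context & calls$depth >= min_depth, ,
                 drop = FALSE]
  if (!nrow(calls)) stop("no qualifying sites for metagene profile")
  cgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank, 0) + 1L, genes$end + flank))
  ov <- GenomicRanges::findOverlaps(cgr, win)
  qi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  pos <- calls$pos[qi]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  plus <- genes$strand[gi] == "+"
  glen <- ge - gs
  # oriented coordinate: negative in upstream flank, [0,1) scaled in body,
  # positive past the gene in downstream flank
  up_off <- ifelse(plus, gs - pos, pos - ge + 1L)      # >0 when upstream
  down_off <- ifelse(plus, pos - ge, gs - pos - 1L)    # >=0 when downstream
  in_body <- pos >= gs & pos < ge
  body_frac <- ifelse(plus, (pos - gs) / glen, (ge - 1L - pos) / glen)
  bin <- integer(length(qi))
  bin[in_body] <- n_flank + 1L + pmin(floor(body_frac[in_body] * body_bins),
                                      body_bins - 1L)
  upstream <- !in_body & up_off > 0
  bin[upstream] <- n_flank - pmin(ceiling(up_off[upstream] / bin_width),
                                  n_flank) + 1L
  downstream <- !in_body & down_off >= 0
  bin[downstream] <- n_flank + body_bins +
    pmin(floor(down_off[downstream] / bin_width), n_flank - 1L) + 1L
  keep <- upstream | in_body | downstream
  bin <- bin[keep]
  f <- factor(bin, levels = seq_len(n_bins))
  dsum <- as.numeric(tapply(calls$depth[qi][keep], f, sum, default = 0))
  msum <- as.numeric(tapply(calls$meth_count[qi][keep], f, sum, default = 0))
  nsit <- as.numeric(tapply(bin, f, length, default = 0))
  level <- ifelse(dsum > 0, msum / dsum, NA_real_)
  zone <- rep(c("upstream", "body", "downstream"),
              c(n_flank, body_bins, n_flank))
  prof <- data.frame(bin = seq_len(n_bins), zone = zone,
                     level = level, smoothed = moving_average(level, 5),
                     n_sites = as.integer(nsit), total_depth = as.integer(dsum))
  class(prof) <- c("gm_metagene", "data.frame")
  attr(prof, "n_flank") <- n_flank
  attr(prof, "body_bins") <- body_bins
  prof
}

#' Centered moving average with edge shrinkage
#'
#' At the series ends the window shrinks symmetrically so no values are
#' fabricated beyond the profile; `NA` bins are ignored within each window.
#'
#' @param x Numeric series.
#' @param k Window size (odd).
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, k = 5) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(x[(i - r):(i + r)], na.rm = TRUE)
  }, numeric(1))
}

#' Plot a metagene profile
#'
#' Dots are per-bin weighted levels; the line is the 5-bin moving average.
#'
#' @param x A `gm_metagene` object.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gm_metagene <- function(x, main = "Metagene CG methylation", ...) {
  n_flank <- attr(x, "n_flank"); body_bins <- attr(x, "body_bins")
  graphics::plot(x$bin, x$level, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "bin (upstream | body | downstream)",
                 ylab = "methylation level", main = main, ...)
  graphics::lines(x$bin, x$smoothed, col = "firebrick", lwd = 2)
  graphics::abline(v = c(n_flank + 0.5, n_flank + body_bins + 0.5), lty = 2)
  graphics::mtext(c("TSS", "TTS"), side = 3,
                  at = c(n_flank + 0.5, n_flank + body_bins + 0.5), cex = 0.8)
  invisible(x)
}

#' Compare per-replicate region levels between two groups
#'
#' Two-sided Welch t-test on per-replicate levels (the significance stars of
#' regional bar plots).  Requires at least two non-missing replicates per
#' group.
#'
#' @param levels_a,levels_b Numeric vectors of per-replicate levels.
#' @return List with `difference` (mean a - mean b), `p_value`, `t`.
#' @export
compare_group_levels <- function(levels_a, levels_b) {
  levels_a <- levels_a[!is.na(levels_a)]; levels_b <- levels_b[!is.na(levels_b)]
  if (length(levels_a) < 2 || length(levels_b) < 2)
    stop("need >= 2 non-missing replicates per group")
  if (stats::var(levels_a) == 0 && stats::var(levels_b) == 0) {
    d <- mean(levels_a) - mean(levels_b)
    return(list(difference = d, p_value = if (d == 0) 1 else 0,
                t = if (d == 0) 0 else sign(d) * Inf))
  }
  tt <- t.test(levels_a, levels_b)
  list(difference = mean(levels_a) - mean(levels_b),
       p_value = tt$p.value, t = unname(tt$statistic))
}

#' Genome-window methylation matrix
#'
#' Tiles every chromosome into fixed non-overlapping windows (default 10 kb)
#' and computes the weighted CG level per window per sample.  Windows where
#' any sample has fewer than `min_sites` qualifying sites are dropped so
#' distances are comparable across samples.
#'
#' @param calls_by_sample Named list of calls `data.frame`s.
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window size in bp (default 10000).
#' @param min_sites Minimum qualifying CG sites per window per sample.
#' @param context,min_depth As in [region_level()].
#' @return Matrix windows x samples, rownames `chrom:start-end`.
#' @export
window_matrix <- function(calls_by_sample, chrom_lengths, window = 10000,
                          min_sites = 5, context = "CG", min_depth = 4) {
  stopifnot(length(calls_by_sample) >= 2)
  tiles <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(0L, chrom_lengths[[ch]] - 1L, by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, chrom_lengths[[ch]]))
  }))
  cols <- lapply(calls_by_sample, function(cc) {
    lv <- region_levels(cc, tiles, context = context, min_depth = min_depth)
    ifelse(lv$n_sites >= min_sites, lv$level, NA_real_)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(calls_by_sample)
  rownames(m) <- sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end)
  m[complete.cases(m), , drop = FALSE]
}

#' Hierarchical clustering and PCA of samples on window methylation
#'
#' Samples are clustered on Euclidean distances between their window-level
#' profiles with Ward's minimum variance linkage (`ward.D2`), and ordinated
#' by PCA of the centered window matrix.
#'
#' @param mat Window matrix from [window_matrix()] (windows x samples).
#' @return List of class `gm_clustering`: `hclust`, `scores` (samples x PCs),
#'   `var_explained`.
#' @export
cluster_and_ordinate <- function(mat) {
  if (ncol(mat) < 3) stop("need >= 3 samples")
  if (nrow(mat) < 10) stop("need >= 10 windows")
  if (all(apply(mat, 1, function(r) max(r) - min(r)) == 0))
    stop("window matrix is constant across samples; ordination undefined")
  d <- dist(t(mat))
  hc <- hclust(d, method = "ward.D2")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(hclust = hc, scores = pc$x, var_explained = ve)
  class(out) <- "gm_clustering"
  out
}

#' @export
print.gm_clustering <- function(x, ...) {
  cat("sample clustering on window methylation\n")
  cat("  samples:", length(x$hclust$labels), "\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}
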