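#' Two-sided Fisher's exact test on pooled methylation counts
#'
#' Tests the 2x2 table `[meth_a, depth_a - meth_a; meth_b, depth_b - meth_b]`.
#' The two-sided p-value sums all hypergeometric point masses not exceeding
#' the observed one (the same definition [stats::fisher.test()] uses), but is
#' computed directly from [stats::dhyper()] so large batches of windows are
#' cheap.
#'
#' @param meth_a,depth_a,meth_b,depth_b Pooled counts (vectorised).
#' @return Two-sided p-value(s).
#' @export
test_window <- function(meth_a, depth_a, meth_b, depth_b) {
  if (any(depth_a <= 0) || any(depth_b <= 0))
    stop("zero depth: Fisher test undefined")
  n <- length(meth_a)
  vapply(seq_len(n), function(i) {
    white <- meth_a[i] + meth_b[i]
    black <- (depth_a[i] - meth_a[i]) + (depth_b[i] - meth_b[i])
    k <- depth_a[i]
    lo <- max(0, k - black); hi <- min(k, white)
    xs <- lo:hi
    pr <- dhyper(xs, white, black, k)
    p_obs <- pr[match(meth_a[i], xs)]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

# Pool replicate call tables by (chrom, pos, strand), CG context only.
pool_cg_calls <- function(calls_list, min_depth = 0) {
  df <- do.call(rbind, lapply(calls_list, function(x)
    x[x$context == "CG", c("chrom", "pos", "strand", "depth", "meth_count")]))
  key <- paste(df$chrom, df$pos, df$strand)
  depth <- rowsum(df$depth, key)
  meth <- rowsum(df$meth_count, key)
  first <- !duplicated(key)
  out <- data.frame(chrom = df$chrom[first], pos = df$pos[first],
                    strand = df$strand[first],
                    depth = depth[match(key[first], rownames(depth)), 1],
                    meth_count = meth[match(key[first], rownames(meth)), 1])
  out <- out[out$depth >= min_depth, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  out$context <- "CG"
  out
}

#' Call differentially methylated regions between two groups
#'
#' Replicates are pooled within each group; candidate windows of `min_cpg`
#' consecutive shared CG sites (depth >= 4 in both pools, neighbour gaps
#' <= `max_gap`) slide one site at a time.  Each window is tested with
#' Fisher's exact test on the pooled counts, p-values are Benjamini-Hochberg
#' adjusted across all tested windows, and windows passing
#' `|delta| >= min_delta` and `q <= max_q` are merged when overlapping or
#' within `max_gap` with the same direction.  Merged regions are re-scored on
#' their full CpG content and must again satisfy every threshold.
#'
#' @param calls_a,calls_b Lists of replicate calls `data.frame`s (or a single
#'   `data.frame`) for groups A and B.
#' @param min_cpg Minimum CG sites per window/region (default 5).
#' @param min_delta Minimum absolute level difference (default 0.25).
#' @param max_q Maximum BH-adjusted p (default 0.05).
#' @param max_gap Maximum distance between consecutive CpGs and for merging
#'   (default 1000 bp).
#' @param min_depth Per-pool site depth filter (default 4).
#' @return `data.frame` of class `gm_dmrs`: `chrom, start, end, n_cpg,
#'   level_a, level_b, delta, p_value, q_value, direction, total_depth`.
#'   `direction` is `"gain"` when group A is more methylated.
#' @export
call_dmrs <- function(calls_a, calls_b, min_cpg = 5, min_delta = 0.25,
                      max_q = 0.05, max_gap = 1000, min_depth = 4) {
  if (is.data.frame(calls_a)) calls_a <- list(calls_a)
  if (is.data.frame(calls_b)) calls_b <- list(calls_b)
  pa <- pool_cg_calls(calls_a, min_depth)
  pb <- pool_cg_calls(calls_b, min_depth)
  key_a <- paste(pa$chrom, pa$pos, pa$strand)
  key_b <- paste(pb$chrom, pb$pos, pb$strand)
  shared <- intersect(key_a, key_b)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpg = integer(), level_a = numeric(),
                      level_b = numeric(), delta = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      direction = character(), total_depth = integer())
  class(empty) <- c("gm_dmrs", "data.frame")
  attr(empty, "n_windows_tested") <- 0L
  if (!length(shared)) return(empty)
  a <- pa[match(shared, key_a), ]; b <- pb[match(shared, key_b), ]
  o <- order(a$chrom, a$pos, a$strand)
  a <- a[o, ]; b <- b[o, ]
  n <- nrow(a)
  if (n < min_cpg) return(empty)
  # candidate windows of min_cpg consecutive sites on one chromosome with
  # every neighbour gap <= max_gap
  same_chrom <- a$chrom[-1] == a$chrom[-n]
  gap_ok <- same_chrom & (a$pos[-1] - a$pos[-n]) <= max_gap
  w <- min_cpg
  starts <- seq_len(n - w + 1L)
  ok <- vapply(starts, function(i) all(gap_ok[i:(i + w - 2L)]), logical(1))
  starts <- starts[ok]
  if (!length(starts)) return(empty)
  attr(empty, "n_windows_tested") <- length(starts)
  cumd_a <- cumsum(a$depth); cumm_a <- cumsum(a$meth_count)
  cumd_b <- cumsum(b$depth); cumm_b <- cumsum(b$meth_count)
  rng <- function(cx, i, j) cx[j] - if (i > 1) cx[i - 1] else 0
  da <- vapply(starts, function(i) rng(cumd_a, i, i + w - 1L), numeric(1))
  ma <- vapply(starts, function(i) rng(cumm_a, i, i + w - 1L), numeric(1))
  db <- vapply(starts, function(i) rng(cumd_b, i, i + w - 1L), numeric(1))
  mb <- vapply(starts, function(i) rng(cumm_b, i, i + w - 1L), numeric(1))
  p <- test_window(ma, da, mb, db)
  q <- p.adjust(p, "BH")
  delta <- ma / da - mb / db
  pass <- abs(delta) >= min_delta & q <= max_q
  if (!any(pass)) return(empty)
  wi <- starts[pass]
  cand <- data.frame(first = wi, last = wi + w - 1L,
                     chrom = a$chrom[wi],
                     start = a$pos[wi], end = a$pos[wi + w - 1L] + 1L,
                     dir = ifelse(delta[pass] > 0, "gain", "loss"))
  # merge same-direction candidates overlapping or within max_gap
  cand <- cand[order(cand$chrom, cand$start), ]
  merged <- list()
  cur <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    nx <- cand[i, ]
    if (nx$chrom == cur$chrom && nx$dir == cur$dir &&
        nx$start <= cur$end + max_gap) {
      cur$end <- max(cur$end, nx$end); cur$last <- max(cur$last, nx$last)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nx
    }
  }
  merged[[length(merged) + 1L]] <- cur
  mg <- do.call(rbind, merged)
  # re-score merged regions on their full CpG content
  ma2 <- vapply(seq_len(nrow(mg)), function(i) rng(cumm_a, mg$first[i], mg$last[i]), numeric(1))
  da2 <- vapply(seq_len(nrow(mg)), function(i) rng(cumd_a, mg$first[i], mg$last[i]), numeric(1))
  mb2 <- vapply(seq_len(nrow(mg)), function(i) rng(cumm_b, mg$first[i], mg$last[i]), numeric(1))
  db2 <- vapply(seq_len(nrow(mg)), function(i) rng(cumd_b, mg$first[i], mg$last[i]), numeric(1))
  p2 <- test_window(ma2, da2, mb2, db2)
  q2 <- p.adjust(p2, "BH")
  delta2 <- ma2 / da2 - mb2 / db2
  n_cpg2 <- mg$last - mg$first + 1L
  res <- data.frame(chrom = mg$chrom, start = mg$start, end = mg$end,
                    n_cpg = n_cpg2, level_a = ma2 / da2, level_b = mb2 / db2,
                    delta = delta2, p_value = p2, q_value = q2,
                    direction = ifelse(delta2 > 0, "gain", "loss"),
                    total_depth = as.integer(da2 + db2))
  keep <- res$n_cpg >= min_cpg & abs(res$delta) >= min_delta &
    res$q_value <= max_q & res$direction == mg$dir
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gm_dmrs", "data.frame")
  attr(res, "n_windows_tested") <- length(starts)
  res
}

#' @export
print.gm_dmrs <- function(x, ...) {
  cat(sprintf("%d DMRs (%d gain, %d loss in group A)\n", nrow(x),
              sum(x$direction == "gain"), sum(x$direction == "loss")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}

#' Validate that every reported DMR satisfies the printed thresholds
#'
#' Post-hoc validator: checks `n_cpg >= min_cpg`, `|delta| >= min_delta` and
#' `q_value <= max_q` for every row.
#'
#' @param dmrs A `gm_dmrs` table.
#' @inheritParams call_dmrs
#' @return `TRUE` invisibly; stops on the first violation.
#' @export
validate_dmrs <- function(dmrs, min_cpg = 5, min_delta = 0.25, max_q = 0.05) {
  bad <- which(dmrs$n_cpg < min_cpg | abs(dmrs$delta) < min_delta |
                 dmrs$q_value > max_q)
  if (length(bad))
    stop("DMR ", bad[1], " violates a reporting threshold")
  invisible(TRUE)
}

#' Map DMRs onto gene regulatory regions
#'
#' A gene is DMR-related for a region type (`upstream2k`, `body`,
#' `downstream2k`) when at least one DMR overlaps that region by >= 1 bp.
#' The net direction per (gene, region type) is the depth-weighted sign of
#' the overlapping DMR deltas; an exact tie is recorded as `"tie"` and such
#' genes are excluded from quadrant classification downstream.
#'
#' @param dmrs A `gm_dmrs` table.
#' @param gene_regions Regions from [derive_gene_regions()].
#' @return `data.frame` with `gene_id, region, n_dmrs, net_score, direction`.
#' @export
assign_dmr_genes <- function(dmrs, gene_regions) {
  reg <- gene_regions[gene_regions$region %in%
                        c("upstream2k", "body", "downstream2k"), , drop = FALSE]
  if (!nrow(dmrs) || !nrow(reg))
    return(data.frame(gene_id = character(), region = character(),
                      n_dmrs = integer(), net_score = numeric(),
                      direction = character()))
  dgr <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  rgr <- GenomicRanges::GRanges(reg$chrom,
                                IRanges::IRanges(reg$start + 1L, reg$end))
  ov <- GenomicRanges::findOverlaps(dgr, rgr)
  di <- S4Vectors::queryHits(ov); ri <- S4Vectors::subjectHits(ov)
  if (!length(di))
    return(data.frame(gene_id = character(), region = character(),
                      n_dmrs = integer(), net_score = numeric(),
                      direction = character()))
  key <- paste(reg$gene_id[ri], reg$region[ri], sep = "\r")
  score <- dmrs$delta[di] * dmrs$total_depth[di]
  agg_score <- rowsum(score, key)
  agg_n <- rowsum(rep(1L, length(di)), key)
  ks <- rownames(agg_score)
  parts <- strsplit(ks, "\r", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    region = vapply(parts, `[`, "", 2L),
                    n_dmrs = as.integer(agg_n[, 1]),
                    net_score = agg_score[, 1])
  out$direction <- ifelse(out$net_score > 0, "gain",
                          ifelse(out$net_score < 0, "loss", "tie"))
  out <- out[order(out$gene_id, out$region), ]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated genes (DMGs)
#'
#' Per gene and region type, compares pooled region methylation between the
#' two groups:
#' `log2_fc = log2((level_a + pseudocount) / (level_b + pseudocount))`, with
#' a Fisher exact p on the pooled counts, BH-adjusted across genes within
#' each region type.  A gene is reported iff `|log2_fc| >= 1` and
#' `fdr <= 0.001`.
#'
#' @param region_counts_a,region_counts_b Output of [region_levels()] on the
#'   pooled group calls over the same `gene_regions` rows (must align).
#' @param pseudocount Added to both levels before the ratio (default 0.01).
#' @param min_lfc,max_fdr Reporting thresholds.
#' @return `data.frame` with `gene_id, region, level_a, level_b,
#'   log2_fc_methylation, p_value, fdr, direction`.
#' @export
call_dmgs <- function(region_counts_a, region_counts_b, pseudocount = 0.01,
                      min_lfc = 1, max_fdr = 0.001) {
  stopifnot(identical(region_counts_a$gene_id, region_counts_b$gene_id),
            identical(region_counts_a$region, region_counts_b$region))
  ok <- region_counts_a$total_depth > 0 & region_counts_b$total_depth > 0
  a <- region_counts_a[ok, ]; b <- region_counts_b[ok, ]
  lfc <- log2((a$level + pseudocount) / (b$level + pseudocount))
  p <- test_window(a$total_meth, a$total_depth, b$total_meth, b$total_depth)
  out <- data.frame(gene_id = a$gene_id, region = a$region,
                    level_a = a$level, level_b = b$level,
                    log2_fc_methylation = lfc, p_value = p)
  out$fdr <- NA_real_
  for (rg in unique(out$region)) {
    sel <- out$region == rg
    out$fdr[sel] <- p.adjust(out$p_value[sel], "BH")
  }
  out$direction <- ifelse(out$log2_fc_methylation > 0, "gain", "loss")
  out <- out[abs(out$log2_fc_methylation) >= min_lfc & out$fdr <= max_fdr, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
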