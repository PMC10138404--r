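#' Classify genes by mean FPKM expression
#'
#' Classes follow the fixed FPKM cut-offs: `high` for mean FPKM >= 100,
#' `middle` for 10 <= FPKM < 100, `low` for 0 < FPKM < 10 and `none` for
#' exactly 0 (a gene with any expression, however small, is `low`).
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param samples Optional character vector of columns to average over
#'   (default: all).
#' @return `data.frame` with `gene_id, fpkm_mean, class`.
#' @export
classify_expression <- function(fpkm, samples = colnames(fpkm)) {
  m <- fpkm[, samples, drop = FALSE]
  if (any(m < 0)) stop("negative FPKM values")
  mu <- rowMeans(m)
  cls <- ifelse(mu >= 100, "high",
                ifelse(mu >= 10, "middle",
                       ifelse(mu > 0, "low", "none")))
  data.frame(gene_id = rownames(fpkm), fpkm_mean = mu, class = cls,
             row.names = NULL)
}

#' Call differentially expressed genes between two groups
#'
#' Fold change on mean FPKM with a pseudocount,
#' `log2_fc = log2((mean_a + pc) / (mean_b + pc))`; the p-value is a
#' two-sided Welch t-test on per-replicate `log2(FPKM + pc)`, BH-adjusted
#' across genes.  A gene is a DEG iff `|log2_fc| >= 1` and `fdr <= 0.05`.
#'
#' @param fpkm_a,fpkm_b FPKM matrices (genes x replicates) for the two
#'   groups, same genes in the same order.
#' @param pseudocount Default 1.
#' @param min_lfc,max_fdr Reporting thresholds.
#' @return List of class `gm_degs`: `table` (all genes) and `degs` (the
#'   reported subset with `direction` `"up"` when group A is higher).
#' @export
call_degs <- function(fpkm_a, fpkm_b, pseudocount = 1, min_lfc = 1,
                      max_fdr = 0.05) {
  stopifnot(identical(rownames(fpkm_a), rownames(fpkm_b)))
  if (ncol(fpkm_a) < 2 || ncol(fpkm_b) < 2)
    stop("need >= 2 replicates per group")
  la <- log2(fpkm_a + pseudocount); lb <- log2(fpkm_b + pseudocount)
  lfc <- log2((rowMeans(fpkm_a) + pseudocount) /
                (rowMeans(fpkm_b) + pseudocount))
  p <- vapply(seq_len(nrow(la)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    t.test(xa, xb)$p.value
  }, numeric(1))
  tab <- data.frame(gene_id = rownames(fpkm_a), log2_fc = lfc, p_value = p,
                    fdr = p.adjust(p, "BH"), row.names = NULL)
  tab$direction <- ifelse(tab$log2_fc > 0, "up", "down")
  degs <- tab[abs(tab$log2_fc) >= min_lfc & tab$fdr <= max_fdr, , drop = FALSE]
  rownames(degs) <- NULL
  out <- list(table = tab, degs = degs)
  class(out) <- "gm_degs"
  out
}

#' @export
print.gm_degs <- function(x, ...) {
  cat(sprintf("%d DEGs of %d genes (%d up, %d down in group A)\n",
              nrow(x$degs), nrow(x$table), sum(x$degs$direction == "up"),
              sum(x$degs$direction == "down")))
  invisible(x)
}

#' Intersect DEGs with DMR-related genes into expression/methylation quadrants
#'
#' For each region type, genes that are both differentially expressed and
#' DMR-related with unambiguous directions are labelled with their joint
#' quadrant: `E+&M+`, `E+&M-`, `E-&M+` or `E-&M-` (E from the DEG direction,
#' M from the net DMR direction; ties are excluded).  Both inputs must come
#' from the same A-vs-B comparison.
#'
#' @param degs A `gm_degs` object (or its `degs` table).
#' @param dmr_genes Output of [assign_dmr_genes()].
#' @return List with `records` (`gene_id, region, quadrant`) and `counts`
#'   (region x quadrant table).
#' @export
intersect_and_classify <- function(degs, dmr_genes) {
  if (inherits(degs, "gm_degs")) degs <- degs$degs
  quadrants <- c("E+&M+", "E+&M-", "E-&M+", "E-&M-")
  dm <- dmr_genes[dmr_genes$direction != "tie", , drop = FALSE]
  rec <- merge(dm, degs[, c("gene_id", "direction")], by = "gene_id",
               suffixes = c("_m", "_e"))
  if (nrow(rec)) {
    rec$quadrant <- paste0("E", ifelse(rec$direction_e == "up", "+", "-"),
                           "&M", ifelse(rec$direction_m == "gain", "+", "-"))
    records <- rec[order(rec$region, rec$gene_id),
                   c("gene_id", "region", "quadrant")]
  } else {
    records <- data.frame(gene_id = character(), region = character(),
                          quadrant = character())
  }
  rownames(records) <- NULL
  counts <- table(factor(records$region,
                         levels = c("upstream2k", "body", "downstream2k")),
                  factor(records$quadrant, levels = quadrants))
  list(records = records, counts = counts)
}

#' Per-CpG-site promoter methylation comparison between two groups
#'
#' Emulates a pyrosequencing-style readout: for every CpG dyad inside a
#' TSS-relative promoter interval, per-replicate methylation levels (plus and
#' minus strand calls pooled per dyad), group means, their difference, and an
#' unadjusted two-sided Welch t p-value per site.  A site is reported only
#' when covered (pooled depth >= `min_depth`) in every replicate of both
#' groups.
#'
#' @param calls_a,calls_b Lists of replicate calls `data.frame`s.
#' @param gene One row of a gene-model `data.frame`.
#' @param from,to TSS-relative offsets of the promoter interval, negative
#'   upstream, half-open `[from, to)` (e.g. `from = -723, to = -480`).
#' @param min_depth Per-replicate pooled dyad depth (default 4).
#' @return `data.frame` with one row per CpG site: `chrom, pos, offset,
#'   level_a, level_b, difference, p_value` plus per-replicate level columns.
#'   Empty (with a warning) when no covered CpG site lies in the interval.
#' @export
promoter_site_comparison <- function(calls_a, calls_b, gene, from, to,
                                     min_depth = 4) {
  stopifnot(from < to)
  if (gene$strand == "+") {
    gstart <- gene$tss + from; gend <- gene$tss + to
  } else {
    gstart <- gene$tss - to + 1L; gend <- gene$tss - from + 1L
  }
  dyad_levels <- function(calls) {
    cg <- calls[calls$context == "CG" & calls$chrom == gene$chrom, ]
    # dyad anchor = plus-strand C position (minus-strand call at p pairs
    # with the plus C at p-1)
    anchor <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
    sel <- anchor >= gstart & anchor < gend
    cg <- cg[sel, ]; anchor <- anchor[sel]
    d <- rowsum(cg$depth, anchor); m <- rowsum(cg$meth_count, anchor)
    data.frame(pos = as.integer(rownames(d)), depth = d[, 1], meth = m[, 1])
  }
  reps <- c(lapply(calls_a, dyad_levels), lapply(calls_b, dyad_levels))
  na <- length(calls_a)
  pos_all <- sort(unique(unlist(lapply(reps, `[[`, "pos"))))
  if (!length(pos_all)) {
    warning("no covered CpG sites in promoter interval")
    return(data.frame(chrom = character(), pos = integer(), offset = integer(),
                      level_a = numeric(), level_b = numeric(),
                      difference = numeric(), p_value = numeric()))
  }
  lev <- sapply(reps, function(r) {
    i <- match(pos_all, r$pos)
    ifelse(!is.na(i) & r$depth[i] >= min_depth, r$meth[i] / r$depth[i],
           NA_real_)
  })
  lev <- matrix(lev, nrow = length(pos_all))
  keep <- rowSums(is.na(lev)) == 0  # covered in all replicates of both groups
  pos_all <- pos_all[keep]; lev <- lev[keep, , drop = FALSE]
  if (!nrow(lev)) {
    warning("no CpG site covered in all replicates")
    return(data.frame(chrom = character(), pos = integer(), offset = integer(),
                      level_a = numeric(), level_b = numeric(),
                      difference = numeric(), p_value = numeric()))
  }
  a <- lev[, seq_len(na), drop = FALSE]
  b <- lev[, -seq_len(na), drop = FALSE]
  pv <- vapply(seq_len(nrow(lev)), function(i) {
    if (stats::var(a[i, ]) == 0 && stats::var(b[i, ]) == 0)
      return(if (mean(a[i, ]) == mean(b[i, ])) 1 else 0)
    t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  offset <- if (gene$strand == "+") pos_all - gene$tss else gene$tss - pos_all
  out <- data.frame(chrom = gene$chrom, pos = pos_all, offset = offset,
                    level_a = rowMeans(a), level_b = rowMeans(b),
                    difference = rowMeans(a) - rowMeans(b), p_value = pv)
  colnames(a) <- paste0("a_rep", seq_len(ncol(a)))
  colnames(b) <- paste0("b_rep", seq_len(ncol(b)))
  cbind(out, a, b)
}
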