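#' CpG island composition thresholds
#'
#' A CpG island must have GC content > 50%, length > 200 bp, and observed/
#' expected CpG ratio > 0.6, where
#' `obs/exp = (#CpG * L) / (#C * #G)`.  `N` bases are excluded from all
#' counts and from the effective length.
#'
#' @param seq A nucleotide string over `{A,C,G,T,N}`.
#' @param min_length,min_gc,min_obs_exp Threshold values.
#' @return List with `gc_fraction`, `obs_exp_cpg`, `n_cpg`, `length`
#'   (N-excluded) and `passes`.
#' @export
check_island_thresholds <- function(seq, min_length = 200, min_gc = 0.5,
                                    min_obs_exp = 0.6) {
  v <- strsplit(toupper(seq), "")[[1]]
  nC <- sum(v == "C"); nG <- sum(v == "G")
  L <- sum(v != "N")
  n_cpg <- sum(v[-length(v)] == "C" & v[-1] == "G")
  gc <- if (L > 0) (nC + nG) / L else 0
  oe <- if (nC > 0 && nG > 0) n_cpg * L / (nC * nG) else NA_real_
  passes <- L > min_length && gc > min_gc && !is.na(oe) && oe > min_obs_exp
  list(gc_fraction = gc, obs_exp_cpg = oe, n_cpg = n_cpg, length = L,
       passes = passes)
}

# O(1) interval statistics over one chromosome, from cumulative counts.
chrom_cumstats <- function(s) {
  v <- strsplit(s, "")[[1]]
  list(C = cumsum(v == "C"), G = cumsum(v == "G"), N = cumsum(v == "N"),
       CG = cumsum(c(v[-length(v)] == "C" & v[-1] == "G", FALSE)),
       len = length(v))
}

# stats of 0-based half-open [a, b); dinucleotides counted fully inside
interval_stats <- function(cs, a, b) {
  rng <- function(x) x[b] - if (a > 0) x[a] else 0
  nC <- rng(cs$C); nG <- rng(cs$G); nN <- rng(cs$N)
  n_cpg <- (if (b - 1 > 0) cs$CG[b - 1] else 0) - (if (a > 0) cs$CG[a] else 0)
  L <- (b - a) - nN
  gc <- if (L > 0) (nC + nG) / L else 0
  oe <- if (nC > 0 && nG > 0) n_cpg * L / (nC * nG) else NA_real_
  list(nC = nC, nG = nG, nN = nN, n_cpg = n_cpg, L = L,
       gc_fraction = gc, obs_exp_cpg = oe)
}

interval_passes <- function(cs, a, b, min_length, min_gc, min_obs_exp) {
  st <- interval_stats(cs, a, b)
  st$L > min_length && st$gc_fraction > min_gc &&
    !is.na(st$obs_exp_cpg) && st$obs_exp_cpg > min_obs_exp
}

#' Detect CpG islands
#'
#' Sliding-window detector in the Takai-Jones style: every 201-bp window
#' (step 1) passing all three composition thresholds seeds an island;
#' overlapping or adjacent seed windows are merged into runs, and each run is
#' revalidated as a whole.  A run failing revalidation is shrunk
#' deterministically by dropping the end seed whose window has the lower
#' observed/expected CpG ratio until the interval passes (a single seed
#' window always does).  Windows containing `N` never seed.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Seed window size in bp (default 201, i.e. the minimal
#'   length exceeding the 200-bp threshold).
#' @param min_length,min_gc,min_obs_exp Island thresholds.
#' @return `data.frame` with `chrom, start, end, kind, gc_fraction,
#'   obs_exp_cpg, n_cpg`.
#' @export
detect_cpg_islands <- function(genome, window = 201, min_length = 200,
                               min_gc = 0.5, min_obs_exp = 0.6) {
  out <- list()
  for (ch in sort(names(genome))) {
    s <- as.character(genome[[ch]])
    cs <- chrom_cumstats(s)
    L <- cs$len
    if (L < window) next
    n_win <- L - window + 1L
    ends <- seq.int(window, L)
    starts0 <- ends - window  # 0-based window starts
    rngv <- function(x) x[ends] - c(0, x[starts0[-1]])
    nC <- rngv(cs$C); nG <- rngv(cs$G); nN <- rngv(cs$N)
    n_cpg <- cs$CG[ends - 1L] - c(0, cs$CG[starts0[-1]])
    Lw <- window - nN
    gc <- (nC + nG) / pmax(Lw, 1)
    oe <- ifelse(nC > 0 & nG > 0, n_cpg * Lw / (nC * nG), NA_real_)
    pass <- nN == 0 & Lw > min_length & gc > min_gc & !is.na(oe) & oe > min_obs_exp
    seeds <- starts0[pass]
    if (!length(seeds)) next
    seed_oe <- oe[pass]
    # connected runs: consecutive seed windows overlap or abut
    brk <- which(diff(seeds) > window)
    run_start <- c(1L, brk + 1L)
    run_end <- c(brk, length(seeds))
    for (r in seq_along(run_start)) {
      i <- run_start[r]; j <- run_end[r]
      while (i < j && !interval_passes(cs, seeds[i], seeds[j] + window,
                                       min_length, min_gc, min_obs_exp)) {
        if (seed_oe[i] <= seed_oe[j]) i <- i + 1L else j <- j - 1L
      }
      a <- seeds[i]; b <- seeds[j] + window
      st <- interval_stats(cs, a, b)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = a, end = b, kind = "island",
        gc_fraction = st$gc_fraction, obs_exp_cpg = st$obs_exp_cpg,
        n_cpg = st$n_cpg)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      kind = character(), gc_fraction = numeric(),
                      obs_exp_cpg = numeric(), n_cpg = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Derive CpG shores and shelves from islands
#'
#' Shores are the 2-kb flanks of each island; shelves the next 2 kb beyond
#' the shores.  Bases are assigned with precedence island > shore > shelf, so
#' features of neighbouring islands never double-count a base; intervals are
#' clipped at chromosome ends.
#'
#' @param islands Island `data.frame` from [detect_cpg_islands()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param flank Flank width in bp (default 2000).
#' @return `data.frame` with `chrom, start, end, kind` for shores and shelves.
#' @export
derive_shores_shelves <- function(islands, chrom_lengths, flank = 2000) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (!nrow(isl)) next
    L <- chrom_lengths[[ch]]
    ir <- IRanges::IRanges(start = isl$start + 1L, end = isl$end)  # 1-based
    if (length(IRanges::reduce(ir, min.gapwidth = 0L)) != length(ir))
      stop("islands must be non-overlapping")
    clip <- function(x) IRanges::restrict(x, start = 1L, end = L)
    shore_zone <- clip(IRanges::reduce(ir + flank))
    shelf_zone <- clip(IRanges::reduce(ir + 2L * flank))
    shores <- IRanges::setdiff(shore_zone, ir)
    shelves <- IRanges::setdiff(IRanges::setdiff(shelf_zone, shore_zone), ir)
    mk <- function(x, kind) if (length(x))
      data.frame(chrom = ch, start = IRanges::start(x) - 1L,
                 end = IRanges::end(x), kind = kind) else NULL
    out[[length(out) + 1L]] <- mk(shores, "shore")
    out[[length(out) + 1L]] <- mk(shelves, "shelf")
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Derive regulatory regions for one gene or all genes
#'
#' Strand-aware regions: `upstream2k` abuts the TSS on the 5' side (for
#' minus-strand genes it lies genomically rightward of the TSS), `body` spans
#' TSS to TTS, `downstream2k` abuts the TTS on the 3' side.  Exons, introns,
#' CDS and UTRs come from the gene model.  Regions are clipped to chromosome
#' bounds when lengths are given.
#'
#' @param genes Gene-model `data.frame` (one or more rows).
#' @param flank Flank length in bp (> 0; default 2000).
#' @param chrom_lengths Optional named lengths for clipping.
#' @return `data.frame` with `gene_id, region, chrom, start, end` (0-based
#'   half-open; one row per interval, so exons/introns give several rows).
#' @export
derive_gene_regions <- function(genes, flank = 2000, chrom_lengths = NULL) {
  if (flank <= 0) stop("flank must be positive")
  rows <- list()
  add <- function(gene_id, region, chrom, start, end) {
    keep <- start < end
    if (any(keep))
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene_id, region = region, chrom = chrom,
        start = start[keep], end = end[keep])
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[g$chrom]] else Inf
    clip_s <- function(x) pmax(x, 0)
    clip_e <- function(x) pmin(x, L)
    if (g$strand == "+") {
      up <- c(g$start - flank, g$start); down <- c(g$end, g$end + flank)
    } else {
      up <- c(g$end, g$end + flank); down <- c(g$start - flank, g$start)
    }
    add(g$gene_id, "upstream2k", g$chrom, clip_s(up[1]), clip_e(up[2]))
    add(g$gene_id, "body", g$chrom, g$start, clip_e(g$end))
    add(g$gene_id, "downstream2k", g$chrom, clip_s(down[1]), clip_e(down[2]))
    es <- exon_vec(g$exon_starts); ee <- exon_vec(g$exon_ends)
    add(g$gene_id, "exon", g$chrom, es, ee)
    if (length(es) > 1)
      add(g$gene_id, "intron", g$chrom, ee[-length(ee)], es[-1])
    if (!is.na(g$cds_start)) {
      # CDS restricted to exonic bases; UTRs are the remaining exonic bases
      exr <- IRanges::IRanges(es + 1L, ee)
      cdsr <- IRanges::intersect(exr, IRanges::IRanges(g$cds_start + 1L, g$cds_end))
      utr <- IRanges::setdiff(exr, cdsr)
      add(g$gene_id, "cds", g$chrom, IRanges::start(cdsr) - 1L, IRanges::end(cdsr))
      if (length(utr)) {
        us <- IRanges::start(utr) - 1L; ue <- IRanges::end(utr)
        before <- ue <= g$cds_start
        lab5 <- if (g$strand == "+") "utr5" else "utr3"
        lab3 <- if (g$strand == "+") "utr3" else "utr5"
        add(g$gene_id, lab5, g$chrom, us[before], ue[before])
        add(g$gene_id, lab3, g$chrom, us[!before], ue[!before])
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), region = character(),
                      chrom = character(), start = integer(), end = integer()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
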