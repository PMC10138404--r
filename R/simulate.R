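#' Default configuration of the synthetic goose-like dataset
#'
#' Scale and noise choices: a 2 x 500 kb toy genome, 200 genes, 40 planted
#' DMRs, mean sequencing depth 30 and a bisulfite conversion error of 0.8%
#' (inside the 0.69-0.88% non-CG methylation range seen in real WGBS of
#' goose muscle).  Two breeds (WZE-like, STE-like) by three stages (E15, E23,
#' P1) by three replicates, with the WZE-like breed demethylating faster over
#' the two later stages.  Expression couples negatively to promoter
#' methylation and the gene body near the TTS is elevated with expression for
#' the non-high classes.
#'
#' @return Named list of generator parameters.
#' @export
gm_default_config <- function() {
  list(
    n_chrom = 2L, chrom_length = 500000L,
    island_density = 1 / 50000,      # ~10 islands per 500 kb chromosome
    n_genes = 200L,
    n_dmrs = 40L, dmr_delta = 0.5, dmr_n_cpg = 8L,
    dmr_discordant_frac = 0.6, dmr_concordant_frac = 0.2,
    n_de = 40L, de_fc = 4,
    mean_depth = 30, conversion_error = 0.008,
    coupling = -9, expr_intercept = 10.5, dispersion = 0.1,
    silent_frac = 0.15,
    noncg_fraction = 0.10,
    breeds = c("WZE", "STE"), stages = c("E15", "E23", "P1"), replicates = 3L,
    # additive global CG offsets per (breed, stage): WZE loses methylation
    # faster between E23 and P1 than STE
    offsets = matrix(c(0, -0.03, -0.08,
                       0, -0.005, -0.02), nrow = 2, byrow = TRUE,
                     dimnames = list(c("WZE", "STE"), c("E15", "E23", "P1"))),
    base_level = 0.78, island_level = 0.10,
    prom_meth_range = c(0.2, 0.95), prom_width = 1200,
    tss_dip_depth = 0.85, tss_dip_width = 350,
    tts_zone_frac = 0.4,
    tts_levels = c(none = 0.52, low = 0.65, middle = 0.78, high = 0.78))
}

#' Generate a synthetic genome with embedded CpG islands
#'
#' Background sequence is CpG-depleted (40% GC with most CpG dinucleotides
#' broken); CpG-rich segments satisfying all three island thresholds
#' (length > 200, GC > 50%, obs/exp CpG > 0.6) are embedded at recorded
#' positions and returned as truth islands.
#'
#' @param n_chrom,chrom_length Genome dimensions (`chrom_length >= 10000`).
#' @param island_density Islands per bp (default 1/25000).
#' @param seed Integer seed.
#' @return List with `genome` ([Biostrings::DNAStringSet]) and `islands`
#'   (truth `data.frame`).
#' @export
generate_genome <- function(n_chrom = 2, chrom_length = 500000,
                            island_density = 1 / 25000, seed = 1) {
  stopifnot(chrom_length >= 10000)
  set.seed(seed)
  n_isl <- round(island_density * chrom_length)
  margin <- min(4000L, chrom_length %/% 10L)
  max_len <- 600
  if (n_isl > 0 && (chrom_length - 2 * margin) / n_isl < max_len + 200)
    stop("island_density too high: islands would overlap")
  seqs <- character(n_chrom)
  truth <- list()
  for (ci in seq_len(n_chrom)) {
    ch <- sprintf("chr%d", ci)
    v <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    # deplete CpG dinucleotides in the background
    cg <- which(v[-chrom_length] == "C" & v[-1] == "G")
    brk <- cg[runif(length(cg)) < 0.75]
    v[brk + 1L] <- "A"
    if (n_isl > 0) {
      slot <- (chrom_length - 2 * margin) / n_isl
      for (k in seq_len(n_isl)) {
        len <- sample(300:max_len, 1)
        at <- margin + round((k - 1) * slot) +
          sample.int(max(1, floor(slot - len)), 1) - 1L
        repeat {
          isl <- island_sequence(len)
          if (check_island_thresholds(isl)$passes) break
        }
        iv <- strsplit(isl, "")[[1]]
        v[(at + 1L):(at + len)] <- iv
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = ch, start = at, end = at + len)
      }
    }
    seqs[ci] <- paste(v, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  islands <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer())
  list(genome = genome, islands = islands)
}

# CpG-enriched sequence: "CG" tokens restore the dinucleotide the background
# lacks; mildly GC-biased single bases keep GC content just above 50%
island_sequence <- function(len) {
  n_tok <- len
  tok <- ifelse(runif(n_tok) < 0.03, "CG",
                sample(c("A", "C", "G", "T"), n_tok, replace = TRUE,
                       prob = c(0.22, 0.28, 0.28, 0.22)))
  s <- paste(tok, collapse = "")
  substr(s, 1, len)
}

#' Generate synthetic gene models
#'
#' Genes are placed on a jittered grid (so 2-kb flanks stay on-chromosome),
#' with alternating strands, 1-4 exons and a CDS spanning the middle of the
#' gene.  One plus-strand gene is designated the pyrosequencing target: the
#' genomic segment at TSS-relative offsets `[-723, -480)` is rewritten to
#' contain exactly 13 CpG sites.
#'
#' @param genome_obj List from [generate_genome()] (genome is modified to
#'   plant the promoter and returned).
#' @param n_genes Total genes (split across chromosomes).
#' @param seed Integer seed.
#' @return List with `genes` (gene-model `data.frame`), `genome` (possibly
#'   rewritten) and `promoter_gene` (the designated gene id).
#' @export
generate_genes <- function(genome_obj, n_genes = 200, seed = 1) {
  set.seed(seed + 1L)
  genome <- genome_obj$genome
  n_chrom <- length(genome)
  per <- ceiling(n_genes / n_chrom)
  rows <- list()
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    ch <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    n_here <- min(per, n_genes - gid)
    usable <- L - 6000
    slot <- floor(usable / n_here)
    for (k in seq_len(n_here)) {
      gid <- gid + 1L
      glen <- sample(1200:min(2400, slot - 200), 1)
      gstart <- 3000L + (k - 1L) * slot + sample.int(slot - glen, 1) - 1L
      gend <- gstart + glen
      strand <- if (gid %% 2L == 0L) "-" else "+"
      n_ex <- sample(1:4, 1)
      if (n_ex == 1) {
        es <- gstart; ee <- gend
      } else {
        cuts <- sort(sample(seq(gstart + 100L, gend - 100L, by = 50L),
                            2L * (n_ex - 1L)))
        es <- c(gstart, cuts[seq(2, length(cuts), by = 2)])
        ee <- c(cuts[seq(1, length(cuts), by = 2)], gend)
      }
      cds_s <- gstart + round(0.2 * glen); cds_e <- gstart + round(0.8 * glen)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = ch, strand = strand,
        start = gstart, end = gend,
        exon_starts = paste(es, collapse = ","),
        exon_ends = paste(ee, collapse = ","),
        cds_start = cds_s, cds_end = cds_e)
    }
  }
  genes <- do.call(rbind, rows)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  # plant the pyrosequencing promoter in a plus-strand gene whose promoter
  # segment does not touch a truth island (the rewrite must not corrupt one)
  cand <- which(genes$strand == "+" & genes$tss > 1000)
  isl <- genome_obj$islands
  clear <- vapply(cand, function(i) {
    a <- genes$tss[i] - 723L; b <- genes$tss[i] - 480L
    !any(isl$chrom == genes$chrom[i] & isl$start < b & isl$end > a)
  }, logical(1))
  cand <- cand[clear]
  pg <- genes[cand[ceiling(length(cand) / 2)], ]
  seg <- promoter_segment_13cg()
  s <- as.character(genome[[pg$chrom]])
  a <- pg$tss - 723L
  substr(s, a + 1L, a + nchar(seg)) <- seg
  gseqs <- as.character(genome)
  gseqs[pg$chrom] <- s
  genome <- Biostrings::DNAStringSet(gseqs)
  list(genes = genes, genome = genome, promoter_gene = pg$gene_id)
}

# 243-bp segment with exactly 13 CpG dinucleotides, A/T elsewhere so no
# accidental CpG forms at the boundaries
promoter_segment_13cg <- function() {
  fill <- 243L - 26L
  gaps <- rep(fill %/% 14L, 14L)
  extra <- fill - sum(gaps)
  if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
  parts <- character(0)
  for (i in seq_len(13L)) {
    parts <- c(parts, strrep("AT", ceiling(gaps[i] / 2)))
    parts[length(parts)] <- substr(parts[length(parts)], 1, gaps[i])
    parts <- c(parts, "CG")
  }
  tailg <- strrep("AT", ceiling(gaps[14L] / 2))
  parts <- c(parts, substr(tailg, 1, gaps[14L]))
  paste(parts, collapse = "")
}

# Enumerate plus-strand CpG dinucleotide positions per chromosome.
cpg_positions <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    m <- Biostrings::matchPattern("CG", genome[[ch]])
    data.frame(chrom = ch, pos = BiocGenerics::start(m) - 1L)
  })
  do.call(rbind, out)
}

#' Build the true methylation surface and expression truths
#'
#' Constructs, per CpG dyad, the true methylation probability: a 0.72
#' background, hypomethylated islands, a Gaussian dip centered on every TSS,
#' per-gene promoter methylation driving expression through a negative
#' coupling, a TTS-proximal gene-body level ordered with expression class for
#' the non-high classes, planted DMR effects between breeds, and additive
#' breed-by-stage global offsets.
#'
#' @param genome,genes,islands Generator outputs.
#' @param config Configuration list ([gm_default_config()]).
#' @param seed Integer seed.
#' @return List with per-dyad `sites` (chrom, pos, base probability),
#'   `prob_by_group` (matrix dyads x breed.stage), `truth` (DMRs, DE genes,
#'   expression, promoter gene).
#' @export
build_surface <- function(genome, genes, islands, config, seed) {
  set.seed(seed + 2L)
  sites <- cpg_positions(genome)
  n <- nrow(sites)
  p0 <- rep(config$base_level, n)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, sites$pos + 2L))
  in_island <- IRanges::overlapsAny(
    sgr, GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(islands$start + 1L,
                                                 islands$end)))
  p0[in_island] <- config$island_level
  # per-gene promoter methylation, uniform over the configured range
  prom_meth <- setNames(runif(nrow(genes), config$prom_meth_range[1],
                              config$prom_meth_range[2]), genes$gene_id)
  # expression baseline: log2 FPKM = intercept + coupling * promoter meth
  base_l2 <- config$expr_intercept + config$coupling * prom_meth +
    rnorm(nrow(genes), 0, 0.5)
  fpkm_true <- 2^base_l2
  silent <- runif(nrow(genes)) < config$silent_frac
  fpkm_true[silent] <- 0
  expr_class <- ifelse(fpkm_true >= 100, "high",
                       ifelse(fpkm_true >= 10, "middle",
                              ifelse(fpkm_true > 0, "low", "none")))
  # paint proximal-promoter methylation and TTS-proximal body levels; the
  # variable (expression-coupled) promoter zone is the prom_width bp nearest
  # the TSS, the remainder of the upstream flank stays at background
  regions <- derive_gene_regions(genes)
  pw <- config$prom_width
  up <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - pw, genes$tss + 1L),
    end = ifelse(genes$strand == "+", genes$tss, genes$tss + 1L + pw))
  ov <- GenomicRanges::findOverlaps(
    sgr, GenomicRanges::GRanges(up$chrom, IRanges::IRanges(up$start + 1L, up$end)))
  p0[S4Vectors::queryHits(ov)] <-
    prom_meth[up$gene_id[S4Vectors::subjectHits(ov)]]
  tts_levels <- config$tts_levels
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    zlen <- round(config$tts_zone_frac * (g$end - g$start))
    zone <- if (g$strand == "+") c(g$end - zlen, g$end) else
      c(g$start, g$start + zlen)
    sel <- sites$chrom == g$chrom & sites$pos >= zone[1] & sites$pos < zone[2]
    p0[sel] <- tts_levels[[expr_class[i]]]
  }
  # Gaussian TSS dip (multiplicative)
  dipf <- rep(1, n)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- which(sites$chrom == g$chrom &
                   abs(sites$pos - g$tss) < 4 * config$tss_dip_width)
    if (length(sel)) {
      d <- exp(-((sites$pos[sel] - g$tss)^2) / (2 * config$tss_dip_width^2))
      dipf[sel] <- pmin(dipf[sel], 1 - config$tss_dip_depth * d)
    }
  }
  p0 <- p0 * dipf
  # DE genes: planted fold change between breeds among expressed genes
  de_cand <- which(fpkm_true >= 10)
  de_idx <- sample(de_cand, min(config$n_de, length(de_cand)))
  de_dir <- rep(c(1, -1), length.out = length(de_idx))
  truth_de <- data.frame(gene_id = genes$gene_id[de_idx],
                         log2_fc = de_dir * log2(config$de_fc))
  # planted DMRs: runs of dmr_n_cpg consecutive dyads inside a regulatory
  # region, neighbour gaps <= 900 bp; base forced to 0.5 so +-delta/2 fits.
  # Hosts are coupled to the DE genes so the joint quadrant structure is
  # discordant-majority: dmr_discordant_frac of DMRs sit on DE genes with a
  # methylation change opposite in sign to the expression change,
  # dmr_concordant_frac with the same sign, and the rest on non-DE genes.
  reg3 <- regions[regions$region %in% c("upstream2k", "body", "downstream2k"), ]
  dmr_eff <- rep(0, n)   # group-A-minus-group-B difference at each dyad
  truth_dmrs <- list()
  used <- rep(FALSE, n)
  n_dis <- round(config$dmr_discordant_frac * config$n_dmrs)
  n_con <- round(config$dmr_concordant_frac * config$n_dmrs)
  de_perm <- sample(seq_along(de_idx))
  host_gene <- character(0); host_sgn <- numeric(0)
  for (j in de_perm) {
    host_gene <- c(host_gene, genes$gene_id[de_idx[j]])
    host_sgn <- c(host_sgn,
                  if (length(host_gene) <= n_dis) -de_dir[j] else de_dir[j])
  }
  other <- sample(setdiff(unique(reg3$gene_id), host_gene))
  host_gene <- c(host_gene[seq_len(min(n_dis + n_con, length(host_gene)))],
                 other)
  host_sgn <- c(host_sgn[seq_len(min(n_dis + n_con, length(host_sgn)))],
                rep(c(1, -1), length.out = length(other)))
  types <- rep(c("upstream2k", "body", "downstream2k"),
               length.out = config$n_dmrs)
  placed <- 0L
  for (h in seq_along(host_gene)) {
    if (placed >= config$n_dmrs) break
    gid <- host_gene[h]
    ty <- types[placed + 1L]
    rr <- reg3[reg3$gene_id == gid & reg3$region == ty, ]
    if (!nrow(rr)) next
    sel <- which(sites$chrom == rr$chrom[1] & sites$pos >= min(rr$start) &
                   sites$pos < max(rr$end) & !used)
    if (length(sel) < config$dmr_n_cpg) next
    k <- config$dmr_n_cpg
    runs <- sel[seq_len(length(sel) - k + 1L)]
    span <- sites$pos[sel[k:length(sel)]] - sites$pos[runs]
    gapok <- vapply(seq_along(runs), function(j) {
      ps <- sites$pos[sel[j:(j + k - 1L)]]
      all(diff(ps) <= 900)
    }, logical(1))
    cand <- which(gapok & span <= 1800)
    if (!length(cand)) next
    idx <- sel[cand[1]:(cand[1] + k - 1L)]
    placed <- placed + 1L
    sgn <- host_sgn[h]
    p0[idx] <- 0.5
    dmr_eff[idx] <- sgn * config$dmr_delta
    used[idx] <- TRUE
    truth_dmrs[[placed]] <- data.frame(
      gene_id = gid, region = ty, chrom = rr$chrom[1],
      start = sites$pos[idx[1]], end = sites$pos[idx[k]] + 2L,
      n_cpg = k, delta = sgn * config$dmr_delta)
  }
  # per-(breed, stage) probabilities
  groups <- expand.grid(breed = config$breeds, stage = config$stages,
                        stringsAsFactors = FALSE)
  prob <- matrix(NA_real_, n, nrow(groups))
  colnames(prob) <- paste(groups$breed, groups$stage, sep = ".")
  for (j in seq_len(nrow(groups))) {
    off <- config$offsets[groups$breed[j], groups$stage[j]]
    half <- if (groups$breed[j] == config$breeds[1]) 0.5 else -0.5
    prob[, j] <- pmin(1, pmax(0, p0 + off + half * dmr_eff))
  }
  list(sites = sites, prob_by_group = prob, groups = groups,
       truth = list(dmrs = if (length(truth_dmrs)) do.call(rbind, truth_dmrs)
                    else data.frame(),
                    de_genes = truth_de,
                    expression = data.frame(gene_id = genes$gene_id,
                                            fpkm_true = fpkm_true,
                                            class = expr_class,
                                            promoter_meth = unname(prom_meth)),
                    fpkm_true = fpkm_true))
}

#' Simulate one methylome sample
#'
#' Per covered cytosine: depth ~ Poisson(`mean_depth`); methylated reads ~
#' Binomial(depth, p_obs) with `p_obs = p_true + (1 - p_true) * err` at CG
#' sites (the error term is unconverted unmethylated cytosine) and
#' `p_obs = err` at non-CG sites.  Rows are strand-specific; both strands of
#' a CpG dyad share the same true probability.  Zero-depth sites are not
#' reported.  Non-CG cytosines are down-sampled to `noncg_sites` fixed
#' positions (shared across samples of one dataset).
#'
#' @param cpg_sites `data.frame` of dyad positions (chrom, pos of the C on
#'   the plus strand).
#' @param p_true True dyad methylation probabilities.
#' @param noncg `data.frame` of non-CG positions with `chrom, pos, strand,
#'   context`.
#' @param mean_depth Mean Poisson depth (>= 1).
#' @param conversion_error Error rate in [0, 0.05].
#' @param seed Integer seed for this sample.
#' @return A calls `data.frame`.
#' @export
simulate_methylome <- function(cpg_sites, p_true, noncg, mean_depth = 30,
                               conversion_error = 0.008, seed = 1) {
  stopifnot(conversion_error >= 0, conversion_error <= 0.05, mean_depth >= 1)
  set.seed(seed)
  err <- conversion_error
  p_obs <- p_true + (1 - p_true) * err
  cg <- rbind(
    data.frame(chrom = cpg_sites$chrom, pos = cpg_sites$pos, strand = "+",
               p = p_obs),
    data.frame(chrom = cpg_sites$chrom, pos = cpg_sites$pos + 1L,
               strand = "-", p = p_obs))
  cg$context <- "CG"
  df <- if (nrow(noncg)) {
    rbind(cg, data.frame(chrom = noncg$chrom, pos = noncg$pos,
                         strand = noncg$strand, p = rep(err, nrow(noncg)),
                         context = noncg$context))
  } else cg
  df$depth <- rpois(nrow(df), mean_depth)
  df <- df[df$depth > 0, ]
  df$meth_count <- rbinom(nrow(df), df$depth, df$p)
  df <- df[order(df$chrom, df$pos, df$strand),
           c("chrom", "pos", "strand", "context", "depth", "meth_count")]
  rownames(df) <- NULL
  df
}

# All non-CG cytosine positions (both strands), down-sampled.
noncg_positions <- function(genome, fraction, seed) {
  set.seed(seed + 3L)
  out <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    v <- strsplit(s, "")[[1]]
    L <- length(v)
    isC <- v == "C"
    nextG <- c(v[-1] == "G", FALSE)
    plus <- which(isC & !nextG)
    isG <- v == "G"
    prevC <- c(FALSE, v[-L] == "C")
    minus <- which(isG & !prevC)
    keep_p <- plus[runif(length(plus)) < fraction]
    keep_m <- minus[runif(length(minus)) < fraction]
    pos <- c(keep_p, keep_m) - 1L
    strand <- rep(c("+", "-"), c(length(keep_p), length(keep_m)))
    ctx <- derive_context(genome, rep(ch, length(pos)), pos, strand)
    ok <- ctx %in% c("CHG", "CHH")
    out[[ch]] <- data.frame(chrom = ch, pos = pos[ok], strand = strand[ok],
                            context = ctx[ok])
  }
  do.call(rbind, out)
}

#' Simulate the FPKM expression matrix
#'
#' Per-gene true FPKM follows the surface (negative promoter coupling);
#' breed B gets the planted fold changes of the truth-DE genes; replicate
#' values are log-normal around the truth with the given dispersion (sd of
#' the natural log).  Silent genes stay exactly 0.
#'
#' @param surface Output of [build_surface()].
#' @param samples Sample sheet `data.frame`.
#' @param config Configuration list.
#' @param seed Integer seed.
#' @return FPKM matrix genes x samples.
#' @export
simulate_expression <- function(surface, samples, config, seed) {
  set.seed(seed + 4L)
  fpkm_true <- surface$truth$fpkm_true
  gene_ids <- surface$truth$expression$gene_id
  de <- surface$truth$de_genes
  m <- matrix(0, length(fpkm_true), nrow(samples),
              dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- fpkm_true
    if (samples$breed[j] == config$breeds[2]) {
      i <- match(de$gene_id, gene_ids)
      mu[i] <- mu[i] / 2^de$log2_fc   # planted FC is breed A over breed B
    }
    noise <- exp(rnorm(length(mu), 0, config$dispersion))
    m[, j] <- ifelse(mu == 0, 0, mu * noise)
  }
  m
}

#' Generate the full synthetic dataset
#'
#' Deterministic in `(config, seed)`: genome with truth islands, gene models
#' with a planted 13-CpG pyrosequencing promoter, the methylation surface,
#' per-sample methylomes (2 breeds x 3 stages x `replicates`), the FPKM
#' matrix, the sample sheet and all truth tables.  The global seed is
#' expanded into independent per-sample substreams.
#'
#' @param config Configuration list; defaults from [gm_default_config()]
#'   (partial lists are merged over the defaults).
#' @param seed Integer master seed.
#' @return List of class `gm_dataset`.
#' @export
simulate_dataset <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(gm_default_config(), config)
  gen <- generate_genome(cfg$n_chrom, cfg$chrom_length, cfg$island_density,
                         seed)
  gg <- generate_genes(gen, cfg$n_genes, seed)
  genome <- gg$genome
  genes <- gg$genes
  surface <- build_surface(genome, genes, gen$islands, cfg, seed)
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         stage = cfg$stages, breed = cfg$breeds,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("breed", "stage", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$breed, samples$stage,
                               samples$replicate)
  samples <- samples[, c("sample_id", "breed", "stage", "replicate")]
  noncg <- noncg_positions(genome, cfg$noncg_fraction, seed)
  set.seed(seed + 5L)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(samples))
  calls <- vector("list", nrow(samples))
  names(calls) <- samples$sample_id
  for (j in seq_len(nrow(samples))) {
    grp <- paste(samples$breed[j], samples$stage[j], sep = ".")
    p <- surface$prob_by_group[, grp]
    calls[[j]] <- simulate_methylome(surface$sites, p, noncg,
                                     cfg$mean_depth, cfg$conversion_error,
                                     sample_seeds[j])
  }
  fpkm <- simulate_expression(surface, samples, cfg, seed)
  truth <- surface$truth
  truth$islands <- gen$islands
  truth$promoter_gene <- gg$promoter_gene
  truth$sample_seeds <- data.frame(sample_id = samples$sample_id,
                                   seed = sample_seeds)
  out <- list(genome = genome, genes = genes, samples = samples,
              calls = calls, fpkm = fpkm, truth = truth, config = cfg,
              seed = seed, surface = surface)
  class(out) <- "gm_dataset"
  out
}

#' @export
print.gm_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic WGBS dataset: %d chrom x %d bp, %d genes, ",
                     "%d samples, %d CpG dyads\n"),
              length(x$genome), x$config$chrom_length, nrow(x$genes),
              nrow(x$samples), nrow(x$surface$sites)))
  cat(sprintf("  planted: %d DMRs, %d DE genes, %d truth islands\n",
              nrow(x$truth$dmrs), nrow(x$truth$de_genes),
              nrow(x$truth$islands)))
  invisible(x)
}

#' Write a dataset to plain-text files
#'
#' FASTA genome, GFF3 gene models, per-sample call TSVs, FPKM TSV, sample
#' sheet and truth tables.
#'
#' @param ds A `gm_dataset`.
#' @param dir Output directory (created).
#' @return `dir` invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(ds$genome, file.path(dir, "genome.fa"))
  write_gene_models_gff3(ds$genes, file.path(dir, "genes.gff3"))
  write.table(ds$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fpkm(ds$fpkm, file.path(dir, "fpkm.tsv"))
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  for (sid in names(ds$calls))
    write_methylation_table(ds$calls[[sid]],
                            file.path(dir, "calls", paste0(sid, ".tsv")))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in c("dmrs", "de_genes", "expression", "islands", "sample_seeds")) {
    tt <- ds$truth[[nm]]
    if (is.data.frame(tt) && nrow(tt))
      write.table(tt, file.path(tdir, paste0(nm, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  writeLines(c(paste0("promoter_gene\t", ds$truth$promoter_gene),
               paste0("seed\t", ds$seed)),
             file.path(tdir, "meta.tsv"))
  invisible(dir)
}
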