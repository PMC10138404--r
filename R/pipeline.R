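#' Read a plain-text key-value configuration file
#'
#' One `key: value` pair per line (`#` comments allowed).  Values are parsed
#' as numbers where possible; everything else stays text.  Keys mirror
#' [gm_default_config()]; unknown keys are rejected.
#'
#' @param path Configuration file.
#' @return Named list suitable for [simulate_dataset()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  known <- names(gm_default_config())
  bad <- setdiff(names(cfg), c(known, "seed"))
  if (length(bad)) stop("unknown config key: ", bad[1])
  cfg
}

stage_log <- function(verbose, ...) if (verbose) message("[goosemethyl] ", ...)

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> validate -> call-mc -> annotate -> profile /
#' windows / cluster -> dmr -> deg -> integrate -> promoter as one
#' reproducible run.  Every output is a plain-text TSV/BED/FASTA/GFF3 file
#' under `out_dir`, and `manifest.json` records the configuration snapshot,
#' seed, package version, per-stage outputs and md5 checksums, so a rerun
#' with the same seed is byte-identical.
#'
#' @param config Configuration list or path to a key-value file (see
#'   [read_config()]); merged over [gm_default_config()].
#' @param out_dir Output directory.
#' @param seed Master seed (overridden by a `seed` entry in the config).
#' @param verbose Emit per-stage progress messages.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(config$seed)) { seed <- as.integer(config$seed); config$seed <- NULL }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "goosemethyl",
                   version = as.character(utils::packageVersion("goosemethyl")),
                   seed = seed, config = utils::modifyList(gm_default_config(),
                                                           config),
                   stages = list())
  paths <- character(0)

  stage_log(verbose, "simulate: generating synthetic dataset (seed ", seed, ")")
  ds <- simulate_dataset(config, seed)
  ddir <- file.path(out_dir, "dataset")
  write_dataset(ds, ddir)
  manifest$stages$simulate <- list(dir = "dataset")

  stage_log(verbose, "validate: checking inputs")
  for (sid in names(ds$calls)) validate_calls(ds$calls[[sid]], sid)
  validate_gene_models(ds$genes)
  check_group_replicates(ds$samples,
                         lapply(seq_len(nrow(unique(ds$samples[2:3]))),
                                function(i) unique(ds$samples[2:3])[i, ]))

  stage_log(verbose, "call-mc: binomial methylcytosine calling")
  mcdir <- file.path(out_dir, "mc"); dir.create(mcdir, showWarnings = FALSE)
  fp_rows <- list()
  for (sid in names(ds$calls)) {
    fp <- estimate_false_positive_rate(ds$calls[[sid]])
    mc <- call_mc(ds$calls[[sid]], fp)
    out <- mc[, c("chrom", "pos", "strand", "context", "depth", "meth_count",
                  "p_value", "is_mc")]
    out$p_value <- signif(out$p_value, 6)
    write.table(out, file.path(mcdir, paste0(sid, ".mc.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fp_rows[[sid]] <- data.frame(sample_id = sid, rate = fp$rate,
                                 n_mCHG = fp$n_mCHG, n_mCHH = fp$n_mCHH,
                                 n_depth = fp$n_depth)
  }
  fp_tab <- do.call(rbind, fp_rows)
  write.table(fp_tab, file.path(out_dir, "false_positive_rates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$call_mc <- list(dir = "mc",
                                  fp_rates = "false_positive_rates.tsv")

  stage_log(verbose, "annotate: CpG islands, shores, shelves, gene regions")
  islands <- detect_cpg_islands(ds$genome)
  chrom_lengths <- setNames(Biostrings::width(ds$genome), names(ds$genome))
  ss <- derive_shores_shelves(islands, chrom_lengths)
  write_bed(data.frame(chrom = islands$chrom, start = islands$start,
                       end = islands$end,
                       name = sprintf("island_%d", seq_len(nrow(islands))),
                       score = pmin(islands$obs_exp_cpg / 2, 1)),
            file.path(out_dir, "islands.bed"))
  if (nrow(ss))
    write_bed(data.frame(chrom = ss$chrom, start = ss$start, end = ss$end,
                         name = sprintf("%s_%d", ss$kind, seq_len(nrow(ss))),
                         score = 0),
              file.path(out_dir, "shores_shelves.bed"))
  regions <- derive_gene_regions(ds$genes, chrom_lengths = chrom_lengths)
  write.table(regions, file.path(out_dir, "gene_regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$annotate <- list(islands = "islands.bed",
                                   shores_shelves = "shores_shelves.bed",
                                   gene_regions = "gene_regions.tsv")

  stage_log(verbose, "profile: metagene methylation")
  pooled_all <- pool_cg_calls(ds$calls)
  prof <- metagene_profile(pooled_all, ds$genes)
  prof_out <- as.data.frame(prof)
  prof_out$level <- signif(prof_out$level, 6)
  prof_out$smoothed <- signif(prof_out$smoothed, 6)
  write.table(prof_out, file.path(out_dir, "metagene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$profile <- list(metagene = "metagene.tsv")

  stage_log(verbose, "windows + cluster: 10-kb matrix, Ward tree, PCA")
  wm <- window_matrix(ds$calls, chrom_lengths)
  wm_out <- data.frame(window = rownames(wm), signif(wm, 6),
                       check.names = FALSE)
  write.table(wm_out, file.path(out_dir, "window_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cl <- cluster_and_ordinate(wm)
  writeLines(hclust_to_newick(cl$hclust), file.path(out_dir, "dendrogram.nwk"))
  sc <- data.frame(sample_id = rownames(cl$scores),
                   signif(cl$scores[, seq_len(min(4, ncol(cl$scores)))], 6))
  write.table(sc, file.path(out_dir, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$cluster <- list(matrix = "window_matrix.tsv",
                                  dendrogram = "dendrogram.nwk",
                                  pca = "pca_scores.tsv")

  breeds <- ds$config$breeds
  quad_files <- list()
  for (st in ds$config$stages) {
    stage_log(verbose, "dmr/deg/integrate: ", breeds[1], " vs ", breeds[2],
              " at ", st)
    ga <- ds$samples$sample_id[ds$samples$breed == breeds[1] &
                                 ds$samples$stage == st]
    gb <- ds$samples$sample_id[ds$samples$breed == breeds[2] &
                                 ds$samples$stage == st]
    dmrs <- call_dmrs(ds$calls[ga], ds$calls[gb])
    validate_dmrs(dmrs)
    dtab <- as.data.frame(dmrs)
    num <- vapply(dtab, is.numeric, logical(1))
    dtab[num] <- lapply(dtab[num], signif, 6)
    write.table(dtab, file.path(out_dir, sprintf("dmrs_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(dmrs))
      write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start,
                           end = dmrs$end,
                           name = sprintf("dmr_%s_%d", st,
                                          seq_len(nrow(dmrs))),
                           score = pmin(abs(dmrs$delta), 1)),
                file.path(out_dir, sprintf("dmrs_%s.bed", st)))
    dmr_genes <- assign_dmr_genes(dmrs, regions)
    degs <- call_degs(ds$fpkm[, ga, drop = FALSE], ds$fpkm[, gb, drop = FALSE])
    deg_out <- degs$degs
    deg_out[c("log2_fc", "p_value", "fdr")] <-
      lapply(deg_out[c("log2_fc", "p_value", "fdr")], signif, 6)
    write.table(deg_out, file.path(out_dir, sprintf("degs_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    integ <- intersect_and_classify(degs, dmr_genes)
    write.table(integ$records,
                file.path(out_dir, sprintf("quadrants_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cnt <- as.data.frame(integ$counts)
    names(cnt) <- c("region", "quadrant", "n")
    write.table(cnt, file.path(out_dir, sprintf("quadrant_counts_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    quad_files[[st]] <- sprintf("quadrants_%s.tsv", st)
  }
  manifest$stages$integrate <- list(quadrants = unname(unlist(quad_files)))

  stage_log(verbose, "promoter: per-CpG-site comparison at the target gene")
  pg <- ds$genes[ds$genes$gene_id == ds$truth$promoter_gene, ]
  st1 <- ds$config$stages[1]
  ga <- ds$samples$sample_id[ds$samples$breed == breeds[1] &
                               ds$samples$stage == st1]
  gb <- ds$samples$sample_id[ds$samples$breed == breeds[2] &
                               ds$samples$stage == st1]
  ps <- promoter_site_comparison(ds$calls[ga], ds$calls[gb], pg, -723, -480)
  num <- vapply(ps, is.numeric, logical(1)) & names(ps) != "pos" &
    names(ps) != "offset"
  ps[num] <- lapply(ps[num], signif, 6)
  write.table(ps, file.path(out_dir, "promoter_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$promoter <- list(table = "promoter_sites.tsv")

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Newick serialisation of an hclust tree (leaf labels, branch lengths from
# merge heights).
hclust_to_newick <- function(hc) {
  lab <- hc$labels
  h <- hc$height
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      l <- node(hc$merge[i, 1], h[i])
      r <- node(hc$merge[i, 2], h[i])
      sprintf("(%s,%s):%g", l, r, parent_h - h[i])
    }
  }
  n <- length(h)
  paste0("(", node(hc$merge[n, 1], h[n]), ",",
         node(hc$merge[n, 2], h[n]), ");")
}
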