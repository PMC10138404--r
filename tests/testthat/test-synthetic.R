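test_that("dataset regeneration from (config, seed) is bit-identical", {
  cfg <- list(chrom_length = 60000L, n_genes = 10L, n_dmrs = 4L, n_de = 6L)
  d1 <- simulate_dataset(cfg, seed = 77)
  d2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(as.character(d1$genome), as.character(d2$genome))
  expect_identical(d1$calls, d2$calls)
  expect_identical(d1$fpkm, d2$fpkm)
  expect_identical(d1$truth$dmrs, d2$truth$dmrs)
  # a different seed changes the data
  d3 <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(as.character(d1$genome), as.character(d3$genome)))
})

test_that("generate_genome honours island density and determinism", {
  g0 <- generate_genome(1, 20000, island_density = 0, seed = 3)
  expect_equal(nrow(g0$islands), 0)
  g1 <- generate_genome(1, 20000, island_density = 1 / 5000, seed = 3)
  expect_equal(nrow(g1$islands), 4)
  # every truth island passes the detector's own thresholds
  s <- as.character(g1$genome[[1]])
  for (i in seq_len(nrow(g1$islands)))
    expect_true(check_island_thresholds(
      substr(s, g1$islands$start[i] + 1, g1$islands$end[i]))$passes)
  expect_error(generate_genome(1, 12000, island_density = 1 / 200, seed = 1),
               "overlap")
})

test_that("simulated non-CG methylation matches the conversion error", {
  ds <- default_dataset()
  nc <- do.call(rbind, lapply(ds$calls[1:3], function(x)
    x[x$context != "CG", c("depth", "meth_count")]))
  expect_gt(nrow(nc), 1e5)
  rate <- sum(nc$meth_count) / sum(nc$depth)
  # within binomial sampling error of the configured 0.8%
  se <- sqrt(0.008 * 0.992 / sum(nc$depth))
  expect_lt(abs(rate - 0.008), 5 * se + 1e-4)
  expect_gt(rate, 0.0069 - 1e-3)  # inside the observed non-CG range
  expect_lt(rate, 0.0088 + 1e-3)
})

test_that("zero conversion error and zero true level give zero meth counts", {
  sites <- data.frame(chrom = "chr1", pos = seq(0, 990, by = 10))
  noncg <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character())
  calls <- simulate_methylome(sites, rep(0, nrow(sites)), noncg,
                              mean_depth = 20, conversion_error = 0, seed = 4)
  expect_true(all(calls$meth_count == 0))
  # and a planted difference of 0.5 is recovered in the pooled fraction
  callsA <- simulate_methylome(sites, rep(0.75, nrow(sites)), noncg,
                               mean_depth = 30, conversion_error = 0, seed = 5)
  callsB <- simulate_methylome(sites, rep(0.25, nrow(sites)), noncg,
                               mean_depth = 30, conversion_error = 0, seed = 6)
  dA <- sum(callsA$meth_count) / sum(callsA$depth)
  dB <- sum(callsB$meth_count) / sum(callsB$depth)
  expect_equal(dA - dB, 0.5, tolerance = 0.03)
})

test_that("expression coupling produces the planted negative correlation", {
  ds <- default_dataset()
  ex <- ds$truth$expression
  expressed <- ex$fpkm_true > 0
  rho <- cor(ex$promoter_meth[expressed], ex$fpkm_true[expressed],
             method = "spearman")
  expect_lt(rho, -0.5)
  # truth-DE genes show the planted fold change between breeds
  de <- ds$truth$de_genes
  wz <- ds$samples$sample_id[ds$samples$breed == "WZE"]
  st <- ds$samples$sample_id[ds$samples$breed == "STE"]
  obs <- log2(rowMeans(ds$fpkm[de$gene_id, wz]) /
                rowMeans(ds$fpkm[de$gene_id, st]))
  expect_equal(obs, de$log2_fc, tolerance = 0.2, ignore_attr = TRUE)
})

test_that("a zero-coupling surface shows no promoter-expression correlation", {
  ds <- simulate_dataset(list(coupling = 0, chrom_length = 200000L,
                              n_genes = 80L, n_dmrs = 0L, n_de = 0L),
                         seed = 31)
  ex <- ds$truth$expression
  expressed <- ex$fpkm_true > 0
  rho <- cor(ex$promoter_meth[expressed], ex$fpkm_true[expressed],
             method = "spearman")
  expect_lt(abs(rho), 0.25)
})

test_that("breed/stage offsets order global levels as configured", {
  ds <- default_dataset()
  lvl <- function(br, st) {
    p <- goosemethyl:::pool_cg_calls(ds$calls[sample_ids(ds, br, st)])
    sum(p$meth_count) / sum(p$depth)
  }
  # STE-like breed stays more methylated at the two later stages
  expect_gt(lvl("STE", "E23"), lvl("WZE", "E23"))
  expect_gt(lvl("STE", "P1"), lvl("WZE", "P1"))
  # and WZE demethylates faster between E23 and P1
  expect_gt(lvl("WZE", "E23") - lvl("WZE", "P1"),
            lvl("STE", "E23") - lvl("STE", "P1"))
})

test_that("planted DMRs and the pyrosequencing promoter are recorded", {
  ds <- default_dataset()
  td <- ds$truth$dmrs
  expect_equal(nrow(td), 40)
  expect_true(all(abs(td$delta) == 0.5))
  expect_true(all(td$n_cpg == 8))
  expect_setequal(unique(td$region), c("upstream2k", "body", "downstream2k"))
  # the planted promoter segment carries exactly 13 CpG dyads
  pg <- ds$genes[ds$genes$gene_id == ds$truth$promoter_gene, ]
  seg <- substr(as.character(ds$genome[[pg$chrom]]),
                pg$tss - 723 + 1, pg$tss - 480)
  v <- strsplit(seg, "")[[1]]
  expect_equal(sum(v[-length(v)] == "C" & v[-1] == "G"), 13)
})

test_that("written dataset files read back consistently", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  expect_identical(as.character(genome), as.character(ds$genome))
  sh <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sh$sample_id, ds$samples$sample_id)
  c1 <- read_methylation_table(
    file.path(dir, "calls", paste0(sh$sample_id[1], ".tsv")), genome = genome)
  expect_equal(as.data.frame(c1), as.data.frame(ds$calls[[1]]),
               ignore_attr = TRUE)
  fp <- read_fpkm(file.path(dir, "fpkm.tsv"))
  expect_equal(fp, ds$fpkm, tolerance = 1e-10)
})
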