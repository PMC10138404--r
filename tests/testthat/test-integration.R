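test_that("expression classes follow the printed FPKM boundaries exactly", {
  fpkm <- matrix(c(100, 99.999, 10, 9.999, 0.001, 0),
                 ncol = 1, dimnames = list(paste0("g", 1:6), "s1"))
  cls <- classify_expression(fpkm)
  expect_equal(cls$class,
               c("high", "middle", "middle", "low", "low", "none"))
  expect_error(classify_expression(matrix(-1, 1, 1,
                                          dimnames = list("g", "s"))),
               "negative")
})

test_that("DEG calling applies fold-change and FDR thresholds", {
  set.seed(3)
  n <- 60
  base <- 2^runif(n, 2, 8)
  a <- sapply(1:3, function(i) base * exp(rnorm(n, 0, 0.1)))
  b <- a
  # plant 6 genes with FC 4 either way; fc below 2 never qualifies
  b[1:3, ] <- a[1:3, ] / 4
  b[4:6, ] <- a[4:6, ] * 4
  b[7, ] <- a[7, ] * 1.9
  rownames(a) <- rownames(b) <- paste0("g", 1:n)
  res <- call_degs(a, b)
  expect_setequal(res$degs$gene_id, paste0("g", 1:6))
  expect_equal(res$degs$direction[res$degs$gene_id == "g1"], "up")
  expect_equal(res$degs$direction[res$degs$gene_id == "g4"], "down")
  expect_false("g7" %in% res$degs$gene_id)  # |log2 1.9| < 1 regardless of p
  expect_error(call_degs(a[, 1, drop = FALSE], b), ">= 2 replicates")
})

test_that("truth-DE genes are recovered from the synthetic data", {
  ds <- default_dataset()
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  res <- call_degs(ds$fpkm[, ga], ds$fpkm[, gb])
  td <- ds$truth$de_genes
  found <- res$degs[match(td$gene_id, res$degs$gene_id), ]
  recall <- mean(!is.na(found$log2_fc) &
                   sign(found$log2_fc) == sign(td$log2_fc))
  expect_gte(recall, 0.9)
  # null comparison within one group: no DEGs expected
  g2 <- sample_ids(ds, "WZE", "E23")
  null2 <- call_degs(ds$fpkm[, g2[1:2], drop = FALSE],
                     ds$fpkm[, g2[3], drop = FALSE][, c(1, 1)])
  expect_lte(nrow(null2$degs), ceiling(0.05 * nrow(ds$fpkm)))
})

test_that("quadrant classification matches the direction label rule", {
  degs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     log2_fc = c(2, -2, 2), p_value = 0, fdr = 0,
                     direction = c("up", "down", "up"))
  dmr_genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                          region = "upstream2k", n_dmrs = 1L,
                          net_score = c(-10, 10, 5, 5),
                          direction = c("loss", "gain", "tie", "gain"))
  res <- intersect_and_classify(degs, dmr_genes)
  expect_equal(res$records$quadrant[res$records$gene_id == "g1"], "E+&M-")
  expect_equal(res$records$quadrant[res$records$gene_id == "g2"], "E-&M+")
  expect_false("g3" %in% res$records$gene_id)  # tie excluded
  expect_false("g4" %in% res$records$gene_id)  # not a DEG
  # counts sum to the number of records per region
  expect_equal(sum(res$counts), nrow(res$records))
  # empty DEG set gives an empty intersection
  empty <- intersect_and_classify(degs[0, ], dmr_genes)
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$counts), 0)
})

test_that("synthetic data yield a discordant-quadrant majority", {
  ds <- default_dataset()
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  lens <- setNames(Biostrings::width(ds$genome), names(ds$genome))
  regions <- derive_gene_regions(ds$genes, chrom_lengths = lens)
  dmrs <- call_dmrs(ds$calls[ga], ds$calls[gb])
  degs <- call_degs(ds$fpkm[, ga], ds$fpkm[, gb])
  res <- intersect_and_classify(degs, assign_dmr_genes(dmrs, regions))
  cnt <- colSums(res$counts)
  discordant <- cnt[["E+&M-"]] + cnt[["E-&M+"]]
  concordant <- cnt[["E+&M+"]] + cnt[["E-&M-"]]
  expect_gt(discordant, concordant)
  # methylation and expression differences point in opposite directions
  up <- res$records[res$records$region == "upstream2k", ]
  expect_gt(nrow(up), 0)
})

test_that("promoter per-site comparison reports the 13 planted CpG sites", {
  ds <- default_dataset()
  pg <- ds$genes[ds$genes$gene_id == ds$truth$promoter_gene, ]
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  tab <- promoter_site_comparison(ds$calls[ga], ds$calls[gb], pg, -723, -480)
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$offset >= -723 & tab$offset < -480))
  expect_true(all(c("a_rep1", "b_rep3") %in% names(tab)))
  # identical groups give zero differences
  same <- promoter_site_comparison(ds$calls[ga], ds$calls[ga], pg, -723, -480)
  expect_true(all(same$difference == 0))
  expect_true(all(same$p_value == 1))
})

test_that("promoter comparison drops incompletely covered sites and warns", {
  ds <- small_dataset()
  pg <- ds$genes[ds$genes$gene_id == ds$truth$promoter_gene, ]
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  tab <- promoter_site_comparison(ds$calls[ga], ds$calls[gb], pg, -723, -480)
  # remove one replicate's coverage of the first site: it must vanish
  drop_pos <- tab$pos[1]
  mod <- ds$calls[ga]
  mod[[1]] <- mod[[1]][!(mod[[1]]$pos %in% c(drop_pos, drop_pos + 1L)), ]
  tab2 <- promoter_site_comparison(mod, ds$calls[gb], pg, -723, -480)
  expect_equal(nrow(tab2), nrow(tab) - 1)
  expect_false(drop_pos %in% tab2$pos)
  # an interval off the chromosome start has no coverage: warn, empty table
  far <- pg$tss + 5000L
  expect_warning(
    out <- promoter_site_comparison(ds$calls[ga], ds$calls[gb], pg,
                                    -far, -far + 500L),
    "no covered CpG")
  expect_equal(nrow(out), 0)
})
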