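test_that("window test equals Fisher's exact test (independent oracle)", {
  expect_equal(test_window(50, 100, 50, 100), 1)
  p <- test_window(90, 100, 10, 100)
  expect_lt(p, 1e-10)
  expect_equal(p, fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value,
               tolerance = 1e-9)
  # exhaustive agreement on all tables with depths <= 12
  for (da in c(1, 3, 5, 8, 12)) for (db in c(1, 4, 7, 12)) {
    for (ma in 0:da) for (mb in 0:db) {
      want <- fisher.test(matrix(c(ma, da - ma, mb, db - mb), 2,
                                 byrow = TRUE))$p.value
      expect_equal(test_window(ma, da, mb, db), want, tolerance = 1e-9)
    }
  }
  # random larger tables
  set.seed(14)
  for (i in 1:50) {
    da <- sample(10:40, 1); db <- sample(10:40, 1)
    ma <- sample(0:da, 1); mb <- sample(0:db, 1)
    want <- fisher.test(matrix(c(ma, da - ma, mb, db - mb), 2,
                               byrow = TRUE))$p.value
    expect_equal(test_window(ma, da, mb, db), want, tolerance = 1e-9)
  }
  expect_error(test_window(0, 0, 1, 10), "zero depth")
})

test_that("BH adjustment matches a reference step-up implementation", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("planted DMRs are recovered and every report satisfies thresholds", {
  ds <- default_dataset()
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  dmrs <- call_dmrs(ds$calls[ga], ds$calls[gb])
  expect_silent(validate_dmrs(dmrs))
  td <- ds$truth$dmrs
  hit <- vapply(seq_len(nrow(td)), function(i) {
    any(dmrs$chrom == td$chrom[i] & dmrs$start < td$end[i] &
          dmrs$end > td$start[i] &
          sign(dmrs$delta) == sign(td$delta[i]))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  # constituent CpG spacing respects the merge gap
  expect_true(all(dmrs$end - dmrs$start <= dmrs$n_cpg * 1000))
})

test_that("DMR calling is symmetric under group swap", {
  ds <- small_dataset()
  ga <- sample_ids(ds, "WZE", "E15"); gb <- sample_ids(ds, "STE", "E15")
  d1 <- call_dmrs(ds$calls[ga], ds$calls[gb])
  d2 <- call_dmrs(ds$calls[gb], ds$calls[ga])
  o1 <- order(d1$chrom, d1$start); o2 <- order(d2$chrom, d2$start)
  expect_equal(d1$start[o1], d2$start[o2])
  expect_equal(d1$end[o1], d2$end[o2])
  expect_equal(d1$delta[o1], -d2$delta[o2], tolerance = 1e-12)
  expect_equal(d1$p_value[o1], d2$p_value[o2], tolerance = 1e-9)
  flip <- c(gain = "loss", loss = "gain")
  expect_equal(unname(flip[d1$direction[o1]]), d2$direction[o2])
})

test_that("null comparisons produce essentially no DMRs", {
  ds <- default_dataset()
  # replicates of the same (breed, stage) split 1+2 vs 3: no true signal
  ga <- sample_ids(ds, "STE", "E15")
  dmrs <- call_dmrs(ds$calls[ga[1]], ds$calls[ga[2]])
  nw <- attr(dmrs, "n_windows_tested")
  expect_gt(nw, 10000)
  expect_lte(nrow(dmrs), 2)
})

test_that("windows with too few CpGs or no shared sites yield nothing", {
  mk <- function(pos, depth, meth) data.frame(
    chrom = "chr1", pos = pos, strand = "+", context = "CG",
    depth = depth, meth_count = meth)
  # only 4 shared CpGs: below the 5-CpG minimum, never reported
  a <- mk(c(0, 100, 200, 300), 30L, 28L)
  b <- mk(c(0, 100, 200, 300), 30L, 2L)
  expect_equal(nrow(call_dmrs(a, b)), 0)
  # disjoint positions: no shared CpGs
  expect_equal(nrow(call_dmrs(mk(0:9 * 100, 30L, 25L),
                              mk(5000 + 0:9 * 100, 30L, 2L))), 0)
  # 8 shared CpGs with a big difference: one DMR
  a8 <- mk(0:7 * 100, 30L, 27L); b8 <- mk(0:7 * 100, 30L, 3L)
  d <- call_dmrs(a8, b8)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_cpg, 8)
  expect_equal(d$direction, "gain")
  expect_gte(d$delta, 0.25)
})

test_that("DMR-to-gene assignment honours overlap and tie rules", {
  regions <- data.frame(
    gene_id = c("g1", "g1", "g2"), region = c("upstream2k", "body", "body"),
    chrom = "chr1", start = c(0L, 2000L, 3500L), end = c(2000L, 4000L, 6000L))
  dmrs <- data.frame(chrom = "chr1", start = c(500L, 3600L), end = c(900L, 3900L),
                     delta = c(0.4, -0.4), total_depth = c(100L, 100L),
                     direction = c("gain", "loss"))
  dg <- assign_dmr_genes(dmrs, regions)
  expect_equal(dg$direction[dg$gene_id == "g1" & dg$region == "upstream2k"],
               "gain")
  # the second DMR overlaps both g1 body and g2 body
  expect_setequal(dg$gene_id[dg$region == "body"], c("g1", "g2"))
  # equal-magnitude opposing DMRs tie
  dmrs2 <- data.frame(chrom = "chr1", start = c(2100L, 2500L),
                      end = c(2300L, 2700L), delta = c(0.4, -0.4),
                      total_depth = c(100L, 100L),
                      direction = c("gain", "loss"))
  dg2 <- assign_dmr_genes(dmrs2, regions)
  expect_equal(dg2$direction[dg2$gene_id == "g1" & dg2$region == "body"], "tie")
})

test_that("DMG calling applies the fold-change and FDR thresholds", {
  mkrc <- function(level, depth) {
    n <- length(level)
    data.frame(gene_id = sprintf("g%02d", seq_len(n)), region = "body",
               level = level, n_sites = 10L, total_depth = depth,
               total_meth = as.integer(round(level * depth)))
  }
  a <- mkrc(c(0.80, 0.50, 0.50), c(4000L, 4000L, 4000L))
  b <- mkrc(c(0.20, 0.50, 0.30), c(4000L, 4000L, 4000L))
  dmg <- call_dmgs(a, b)
  expect_equal(dmg$gene_id, "g01")
  expect_equal(dmg$log2_fc_methylation, log2(0.81 / 0.21), tolerance = 1e-9)
  expect_equal(dmg$direction, "gain")
  # equal levels are never reported; 0.5 vs 0.3 fails |lfc| >= 1
  expect_false(any(dmg$gene_id %in% c("g02", "g03")))
  # zero level in one group stays finite through the pseudocount
  a2 <- mkrc(c(0.5), 4000L); b2 <- mkrc(c(0.0), 4000L)
  dmg2 <- call_dmgs(a2, b2)
  expect_true(is.finite(dmg2$log2_fc_methylation))
  expect_equal(dmg2$log2_fc_methylation, log2(0.51 / 0.01), tolerance = 1e-9)
})
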