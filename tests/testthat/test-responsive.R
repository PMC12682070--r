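test_that("promoter bins tile the 2-kb upstream window strand-aware", {
  fx <- responsive_fixture()
  pb <- promoter_bin_diffs(fx$genes, fx$immature, fx$ripe)
  bins <- pb$bins
  expect_equal(nrow(bins), 6L * 20L)
  # plus strand: bin 1 ends at TSS - 1, bin 20 starts at TSS - 2000
  g1 <- bins[gene_id == "g1"]
  expect_equal(g1[bin == 1L, start], 10000L - 100L)
  expect_equal(g1[bin == 1L, end], 10000L - 1L)
  expect_equal(g1[bin == 20L, start], 10000L - 2000L)
  expect_equal(sum(g1$end - g1$start + 1L), 2000L)
  # minus strand: bin 1 sits just above the TSS (the gene end)
  g6 <- bins[gene_id == "g6"]
  expect_equal(g6[bin == 1L, start], 50999L + 1L)
  expect_equal(g6[bin == 1L, end], 50999L + 100L)
  expect_equal(g6[bin == 20L, end], 50999L + 2000L)
})

test_that("bin differences are exact on the designed fixture", {
  fx <- responsive_fixture()
  pb <- promoter_bin_diffs(fx$genes, fx$immature, fx$ripe)
  bins <- pb$bins
  expect_equal(bins[gene_id == "g1" & bin == 1L, difference], 0.06)
  expect_equal(bins[gene_id == "g2" & bin == 5L, difference], 0.20)
  expect_equal(bins[gene_id == "g3" & bin == 7L, difference], -0.06)
  expect_equal(bins[gene_id == "g5", unique(difference)], 0)
  # differential only beyond |0.05|
  expect_true(bins[gene_id == "g1" & bin == 1L, differential])
  expect_false(bins[gene_id == "g5" & bin == 1L, differential])
  # a bin at immature 5/50 vs ripe 12/60 differs by exactly 0.1
  im <- list(methylome(data.table(chrom = "c", pos = 8950L, strand = "+",
                                  n_meth = 5L, n_unmeth = 45L,
                                  subcontext = "CAA")))
  rp <- list(methylome(data.table(chrom = "c", pos = 8950L, strand = "+",
                                  n_meth = 12L, n_unmeth = 48L,
                                  subcontext = "CAA")))
  gene <- data.table(gene_id = "g", chrom = "c", start = 9000L,
                     end = 9500L, strand = "+", id = "g")
  pb2 <- promoter_bin_diffs(gene, im, rp)
  expect_equal(pb2$bins[bin == 1L, difference], 0.1)
  expect_true(pb2$bins[bin == 1L, differential])
})

test_that("responsive calls on the six-gene fixture equal the designed truth", {
  fx <- responsive_fixture()
  pb <- promoter_bin_diffs(fx$genes, fx$immature, fx$ripe)
  calls <- call_responsive_genes(pb)
  got <- calls[order(gene_id)]
  expect_equal(got$gene_id, fx$truth$gene_id)
  expect_equal(got$responsive_hyper, fx$truth$hyper)
  expect_equal(got$responsive_hypo, fx$truth$hypo)
  # the single large bin of g2 is not enough
  expect_false(got[gene_id == "g2", responsive_hyper])
  expect_equal(got[gene_id == "g2", n_diff_bins_hyper], 1L)
  # mixed-direction g3 is responsive in neither direction
  expect_false(got[gene_id == "g3", responsive_hyper])
  expect_false(got[gene_id == "g3", responsive_hypo])
  # gene-level difference is the mean over differential bins
  expect_equal(got[gene_id == "g1", gene_mchh_difference], 0.06)
  expect_equal(got[gene_id == "g4", gene_mchh_difference], -0.08)
  expect_equal(got[gene_id == "g3", gene_mchh_difference], 0)
  # idempotent and order-invariant
  calls2 <- call_responsive_genes(pb)
  expect_equal(as.data.frame(calls), as.data.frame(calls2))
})

test_that("zero-coverage bins are undefined and never differential", {
  im <- list(methylome(data.table(chrom = "c", pos = 8950L, strand = "+",
                                  n_meth = 0L, n_unmeth = 10L,
                                  subcontext = "CAA")))
  rp <- list(methylome(data.table(chrom = "c", pos = 8850L, strand = "+",
                                  n_meth = 10L, n_unmeth = 0L,
                                  subcontext = "CAA")))
  gene <- data.table(gene_id = "g", chrom = "c", start = 9000L, end = 9500L,
                     strand = "+", id = "g")
  pb <- promoter_bin_diffs(gene, im, rp)
  expect_true(all(is.na(pb$bins$difference)))
  expect_false(any(pb$bins$differential))
  calls <- call_responsive_genes(pb)
  expect_false(calls$responsive_hyper)
  expect_equal(calls$n_diff_bins, 0L)
})

test_that("tissue-specificity categories cross the two hyper flags", {
  mk <- function(ids, hyper) {
    data.table(gene_id = ids, responsive_hyper = hyper,
               responsive_hypo = FALSE, n_diff_bins_hyper = 2L,
               n_diff_bins_hypo = 0L, n_diff_bins = 2L,
               gene_mchh_difference = 0.1)
  }
  pulp <- mk(c("a", "b", "c", "d"), c(TRUE, TRUE, FALSE, FALSE))
  skin <- mk(c("a", "b", "c", "d"), c(TRUE, FALSE, TRUE, FALSE))
  cats <- classify_gene_tissue_specificity(pulp, skin)
  expect_equal(cats[order(gene_id), category],
               c("common", "pulp_specific", "skin_specific", "none"))
  expect_warning(
    classify_gene_tissue_specificity(mk("a", TRUE), mk("b", TRUE)),
    "one call set only")
})

test_that("expression integration counts tissue-restricted DE per category", {
  cats <- data.table(gene_id = c("p1", "p2", "s1", "c1", "c2", "n1"),
                     category = c("pulp_specific", "pulp_specific",
                                  "skin_specific", "common", "common",
                                  "none"))
  expr <- rbindlist(list(
    data.table(gene_id = "p1", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = c(2.5, 10),
               de_direction = c("down", "none")),
    data.table(gene_id = "p2", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = c(40, 40),
               de_direction = c("up", "up")),       # DE in both: excluded
    data.table(gene_id = "s1", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = c(10, 40),
               de_direction = c("none", "up")),
    data.table(gene_id = "c1", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = c(2.5, 2.5),
               de_direction = c("down", "down")),
    data.table(gene_id = "c2", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = c(40, 10),
               de_direction = c("up", "none")),     # common but pulp-only DE
    data.table(gene_id = "n1", tissue = c("pulp", "skin"),
               fpkm_immature = 10, fpkm_ripe = 10,
               de_direction = "none")))
  res <- integrate_expression(cats, expr)
  cnt <- res$counts
  expect_equal(cnt[category == "pulp_specific" & de_pattern == "down", n], 1L)
  expect_equal(cnt[category == "pulp_specific" & de_pattern == "up", n], 0L)
  expect_equal(cnt[category == "skin_specific" & de_pattern == "up", n], 1L)
  expect_equal(cnt[category == "common" & de_pattern == "down", n], 1L)
  # a common gene DE in one tissue only is excluded from the cross-tab
  expect_equal(res$genes[gene_id == "c2", de_pattern], "excluded")
  # no DE at all: all zero
  expr0 <- copy(expr)[, de_direction := "none"]
  res0 <- integrate_expression(cats, expr0)
  expect_true(all(res0$counts$n == 0L))
})

test_that("inactive genes with planted methylation separate from active", {
  set.seed(9)
  genes <- data.table(gene_id = sprintf("g%02d", 1:20), chrom = "chrA",
                      start = seq(5000L, 81000L, by = 4000L))
  genes[, `:=`(end = start + 999L, strand = "+", id = gene_id)]
  active <- rep(c(TRUE, FALSE), 10L)
  # methylation high over body+promoter of inactive genes
  regions <- genes[!active, .(start = start - 2000L, end = end)]
  m <- patterned_methylome(90000L, regions, level_in = 0.6,
                           level_out = 0.05, tissue = "pulp",
                           stage = "immature")
  expr <- data.table(gene_id = genes$gene_id, tissue = "pulp",
                     fpkm_immature = ifelse(active, 20, 0.2),
                     fpkm_ripe = ifelse(active, 20, 0.2),
                     de_direction = "none")
  res <- active_inactive_summary(expr, genes, m)
  tst <- res$tests[context == "CHH"]
  expect_true(all(tst$median_inactive > tst$median_active))
  expect_true(all(tst$p_value < 0.001))
  # identical methylation for all genes: no separation
  m2 <- patterned_methylome(90000L, regions[0], level_in = 0.3,
                            level_out = 0.3, tissue = "pulp",
                            stage = "immature")
  res2 <- active_inactive_summary(expr, genes, m2)
  expect_true(all(res2$tests[context == "CHH", p_value] > 0.5))
  # all genes active: comparison unavailable
  expr_act <- copy(expr)[, fpkm_immature := 20]
  res3 <- active_inactive_summary(expr_act, genes, m)
  expect_true(all(is.na(res3$tests$p_value)))
})
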