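test_that("global levels are coverage-weighted and per-context", {
  m <- methylome(data.table(
    chrom = "c", pos = c(10L, 20L, 30L), strand = "+",
    n_meth = c(3L, 7L, 5L), n_unmeth = c(7L, 3L, 0L),
    subcontext = c("CGA", "CGT", "CAA")))
  g <- global_levels(m)
  expect_equal(g[context == "CG", weighted_level], 10 / 20)
  expect_equal(g[context == "CHH", weighted_level], 1)
  expect_true(is.na(g[context == "CHG", weighted_level]))
  expect_equal(g[context == "all", weighted_level], 15 / 25)
  # saturation: everything fully methylated
  sat <- constant_methylome(lvl_num = 2L, lvl_den = 2L)
  expect_true(all(global_levels(sat)[n_sites > 0, weighted_level] == 1))
})

test_that("genome binning tiles chromosomes and measures density", {
  m <- constant_methylome(len = 2500L)
  tr <- bin_genome(m, bin_size = 1000L, seqlengths = c(chrA = 2500L))
  expect_equal(tr$start, c(1L, 1001L, 2001L))
  expect_equal(tr$end, c(1000L, 2000L, 2500L))
  # constant 50% methylome: every covered bin at exactly 0.5 in all contexts
  for (ctx in c("CG", "CHG", "CHH")) {
    lv <- tr[[paste0("level_", ctx)]]
    expect_true(all(abs(lv[!is.na(lv)] - 0.5) < 1e-15))
  }
  ann <- annotation_set(
    data.table(chrom = "chrA", start = 101L, end = 500L, strand = "+",
               id = "g1"),
    NULL, c(chrA = 2500L))
  tr2 <- bin_genome(m, bin_size = 1000L, annotations = ann)
  expect_equal(tr2$gene_density, c(0.4, 0, 0))
})

test_that("weighted global level equals the weighted mean of bin levels", {
  st <- small_study()
  m <- st$samples$pulp_immature_rep1
  for (bs in c(1000L, 5000L)) {
    tr <- bin_genome(m, bin_size = bs,
                     seqlengths = st$annotations$seqlengths)
    g <- global_levels(m)
    for (ctx in c("CG", "CHH")) {
      lv <- tr[[paste0("level_", ctx)]]
      w <- tr[[paste0("cov_", ctx)]]
      ok <- !is.na(lv)
      expect_equal(sum(lv[ok] * w[ok]) / sum(w[ok]),
                   g[context == ctx, weighted_level], tolerance = 1e-12)
    }
  }
})

test_that("replicate correlation behaves at the identity and its mirror", {
  m <- small_study()$samples$pulp_immature_rep1
  tr <- bin_genome(m, bin_size = 1000L,
                   seqlengths = small_study()$annotations$seqlengths)
  expect_equal(replicate_correlation(tr, tr, "CG")$r, 1.0)
  anti <- data.table::copy(tr)
  anti[, level_CG := 1 - level_CG]
  expect_equal(replicate_correlation(tr, anti, "CG")$r, -1.0)
  expect_error(replicate_correlation(tr[1:2], tr[1:2], "CG"), "fewer than 3")
})

test_that("two simulated replicates correlate strongly at 1-kb bins", {
  st <- small_study()
  t1 <- bin_genome(st$samples$pulp_immature_rep1, 1000L,
                   seqlengths = st$annotations$seqlengths)
  t2 <- bin_genome(st$samples$pulp_immature_rep2, 1000L,
                   seqlengths = st$annotations$seqlengths)
  expect_gt(replicate_correlation(t1, t2, "CG")$r, 0.9)
})

test_that("metagene profile is flat on a constant methylome", {
  m <- constant_methylome(len = 30000L, every = 3L)
  feats <- data.table(chrom = "chrA",
                      start = c(5000L, 12000L, 21000L),
                      end = c(7000L, 15000L, 22500L),
                      strand = c("+", "-", "+"),
                      id = c("a", "b", "c"))
  pr <- metagene_profile(m, feats)
  lv <- pr[context == "CG" & !is.na(level), level]
  expect_true(length(lv) > 70)
  expect_lte(max(lv) - min(lv), 1e-12)
})

test_that("metagene profile is invariant to feature order and localises", {
  m <- constant_methylome(len = 30000L, every = 3L)
  feats <- data.table(chrom = "chrA",
                      start = c(5000L, 12000L, 21000L),
                      end = c(7000L, 15000L, 22500L),
                      strand = c("+", "-", "+"),
                      id = c("a", "b", "c"))
  p1 <- metagene_profile(m, feats)
  p2 <- metagene_profile(m, feats[c(3, 1, 2)])
  expect_equal(as.data.frame(p1), as.data.frame(p2))

  # methylation only upstream of a plus-strand feature stays upstream
  sites <- data.table(chrom = "chrA", pos = seq.int(3000L, 4990L, 10L),
                      strand = "+", n_meth = 50L, n_unmeth = 50L,
                      subcontext = "CAA")
  body <- data.table(chrom = "chrA", pos = seq.int(5000L, 9000L, 10L),
                     strand = "+", n_meth = 0L, n_unmeth = 100L,
                     subcontext = "CAA")
  m2 <- methylome(rbind(sites, body))
  pr <- metagene_profile(m2, data.table(chrom = "chrA", start = 5000L,
                                        end = 7000L, strand = "+",
                                        id = "a"))
  up <- pr[context == "CHH" & bin_index <= 20]
  rest <- pr[context == "CHH" & bin_index > 20]
  expect_true(all(up[!is.na(level), level] == 0.5))
  expect_true(all(rest[!is.na(level), level] == 0))
})

test_that("metagene profile is unchanged under genome mirroring", {
  len <- 30000L
  m <- constant_methylome(len = len, every = 3L)
  # vary levels along the chromosome so the profile is informative
  s <- data.table::copy(m$sites)
  s[, n_meth := as.integer(pos %% 7 < 3) * 2L]
  s[, n_unmeth := 4L - n_meth]
  m <- methylome(s)
  feats <- data.table(chrom = "chrA", start = c(5000L, 16000L),
                      end = c(8000L, 18000L), strand = c("+", "-"),
                      id = c("a", "b"))
  pr <- metagene_profile(m, feats)
  # mirror: position p -> len + 1 - p, strands flipped
  sm <- data.table::copy(m$sites)
  sm[, pos := len + 1L - pos]
  sm[, strand := ifelse(strand == "+", "-", "+")]
  mm <- methylome(sm)
  fm <- data.table(chrom = "chrA",
                   start = len + 1L - feats$end,
                   end = len + 1L - feats$start,
                   strand = ifelse(feats$strand == "+", "-", "+"),
                   id = feats$id)
  prm <- metagene_profile(mm, fm)
  expect_equal(pr$level, prm$level)
  expect_equal(pr$coverage, prm$coverage)
})

test_that("region-centred profile is flat on constant input and peaks where planted", {
  m <- constant_methylome(len = 30000L, every = 3L)
  regions <- data.table(chrom = "chrA", start = c(8000L, 20000L),
                        end = c(8400L, 20600L))
  pr <- region_centered_profile(m, regions)
  expect_equal(max(pr$bin_index), 41L)
  lv <- pr[context == "CHH" & !is.na(level), level]
  expect_lte(max(lv) - min(lv), 1e-12)

  m2 <- patterned_methylome(30000L,
                            data.table(start = 9950L, end = 10050L),
                            level_in = 0.8, level_out = 0.05)
  pr2 <- region_centered_profile(m2, data.table(chrom = "chrA",
                                                start = 9950L,
                                                end = 10050L))
  center <- pr2[context == "CHH" & bin_index == 21L, level]
  flank <- pr2[context == "CHH" & bin_index %in% c(1L, 41L), level]
  expect_gt(center, 0.7)
  expect_true(all(flank < 0.1))
})

test_that("subcontext summary reports density and level per trinucleotide", {
  m <- methylome(data.table(
    chrom = "c", pos = c(10L, 20L, 30L, 40L), strand = "+",
    n_meth = c(3L, 3L, 3L, 0L), n_unmeth = c(7L, 7L, 7L, 10L),
    subcontext = c("CAA", "CAA", "CAA", "CCC")))
  sc <- subcontext_summary(m)
  expect_equal(nrow(sc), 16L)
  expect_equal(sc[subcontext == "CAA", density], 0.75)
  expect_equal(sc[subcontext == "CAA", weighted_level], 0.3)
  expect_equal(sc[subcontext == "CCC", weighted_level], 0)
  expect_equal(sum(sc$density), 1)
  # a CGA-only sample concentrates all density there
  cga <- methylome(data.table(chrom = "c", pos = c(5L, 15L), strand = "+",
                              n_meth = 1L, n_unmeth = 1L,
                              subcontext = "CGA"))
  expect_equal(subcontext_summary(cga)[subcontext == "CGA", density], 1)
})

test_that("simulator subcontext ordering puts CAA and CTA above CCC", {
  st <- small_study()
  sc <- subcontext_summary(st$samples$pulp_immature_rep1)
  expect_gt(sc[subcontext == "CAA", weighted_level],
            sc[subcontext == "CCC", weighted_level])
  expect_gt(sc[subcontext == "CTA", weighted_level],
            sc[subcontext == "CCC", weighted_level])
})
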