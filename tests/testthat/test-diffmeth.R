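test_that("the site LRT matches the closed-form oracle on worked cases", {
  r <- lrt_site_test(list(c(2, 20), c(3, 20)), list(c(10, 20), c(12, 20)))
  o <- oracle_lrt(5, 40, 22, 40)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
  expect_equal(r$statistic, 17.11, tolerance = 0.005)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  expect_equal(r$p_value, 3.5e-5, tolerance = 0.1)
  expect_equal(r$difference, 22 / 40 - 5 / 40)

  # identical pooled proportions: statistic 0, p 1
  same <- lrt_site_test(list(c(3, 10)), list(c(6, 20)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # extreme separation
  ext <- lrt_site_test(list(c(0, 10)), list(c(10, 10)))
  expect_equal(ext$difference, 1.0)
  expect_lt(ext$p_value, 1e-4)
  oext <- oracle_lrt(0, 10, 10, 10)
  expect_equal(ext$statistic, oext$statistic, tolerance = 1e-9)
})

test_that("the LRT rejects degenerate replicate input", {
  expect_error(lrt_site_test(list(c(1, 0)), list(c(1, 2))), "total")
  expect_error(lrt_site_test(list(c(3, 2)), list(c(1, 2))), "count")
  expect_error(lrt_site_test(list(), list(c(1, 2))))
})

test_that("swapping groups flips differences and directions, not p-values", {
  set.seed(11)
  for (i in 1:20) {
    t_a <- sample(5:40, 1); t_b <- sample(5:40, 1)
    m_a <- sample.int(t_a, 1) - 1L; m_b <- sample.int(t_b, 1) - 1L
    f <- lrt_pooled(m_a, t_a, m_b, t_b)
    r <- lrt_pooled(m_b, t_b, m_a, t_a)
    expect_equal(f$difference, -r$difference)
    expect_equal(f$p_value, r$p_value, tolerance = 1e-12)
  }
})

# builds one replicate methylome from per-site (m, t) CHH counts at fixed
# positions
counts_methylome <- function(pos, m, t, ...) {
  methylome(data.table(chrom = "chr1", pos = pos, strand = "+",
                       n_meth = as.integer(m),
                       n_unmeth = as.integer(t - m), subcontext = "CAA"),
            ...)
}

test_that("DMC calling enforces both the context threshold and the p cutoff", {
  pos <- c(100L, 200L, 300L)
  # site 1: CHH diff +0.04 with overwhelming evidence -> below threshold
  # site 2: CHH diff +0.30, strong evidence -> hyper call
  # site 3: CHH diff +0.30 but weak evidence (low coverage) -> p too large
  a1 <- counts_methylome(pos, m = c(100L, 10L, 1L),
                         t = c(1000L, 100L, 5L))
  a2 <- counts_methylome(pos, m = c(100L, 10L, 1L),
                         t = c(1000L, 100L, 5L))
  b1 <- counts_methylome(pos, m = c(140L, 40L, 2L),
                         t = c(1000L, 100L, 5L))
  b2 <- counts_methylome(pos, m = c(140L, 40L, 3L),
                         t = c(1000L, 100L, 5L))
  calls <- call_dmcs(list(a1, a2), list(b1, b2))
  expect_equal(calls$pos, 200L)
  expect_equal(calls$direction, "hyper")
  expect_equal(calls$difference, 0.3)
  # verify the skipped sites for the stated reasons
  p1 <- lrt_pooled(200, 2000, 280, 2000)
  expect_lt(p1$p_value, 0.05)          # significant ...
  expect_lt(abs(p1$difference), 0.05)  # ... but below the CHH threshold
  p3 <- lrt_pooled(2, 10, 5, 10)
  expect_gt(abs(p3$difference), 0.05)  # above threshold ...
  expect_gt(p3$p_value, 0.05)          # ... but not significant
})

test_that("the comparison universe is the intersection across replicates", {
  a1 <- counts_methylome(c(100L, 200L), m = c(0L, 0L), t = c(50L, 50L))
  a2 <- counts_methylome(100L, m = 0L, t = 50L)     # site 200 missing
  b1 <- counts_methylome(c(100L, 200L), m = c(40L, 40L), t = c(50L, 50L))
  b2 <- counts_methylome(c(100L, 200L), m = c(40L, 40L), t = c(50L, 50L))
  calls <- call_dmcs(list(a1, a2), list(b1, b2))
  expect_equal(calls$pos, 100L)
  expect_warning(
    out <- call_dmcs(list(counts_methylome(1L, 0L, 50L)),
                     list(counts_methylome(500L, 40L, 50L))),
    "no sites shared")
  expect_equal(nrow(out), 0L)
})

test_that("DMR construction matches the worked fixtures", {
  cfg <- comparison_config()
  # 12 DMCs at 1000, 1010, ..., 1110: one region trimmed to the sites
  d12 <- make_dmcs(seq(1000L, 1110L, 10L))
  r <- call_dmrs(d12, cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 1110L)
  expect_equal(r$n_dmcs, 12L)
  # 9 tightly clustered DMCs never reach the 10-DMC requirement
  d9 <- make_dmcs(seq(1000L, 1080L, 10L))
  expect_equal(nrow(call_dmrs(d9, cfg)), 0L)
  # empty in, empty out
  expect_equal(nrow(call_dmrs(d12[0], cfg)), 0L)
})

test_that("DMR calling is order-invariant and separates directions", {
  cfg <- comparison_config()
  d <- rbind(make_dmcs(seq(1000L, 1110L, 10L), "hyper"),
             make_dmcs(seq(1005L, 1115L, 10L), "hypo"))
  set.seed(3)
  shuffled <- d[sample(nrow(d))]
  r1 <- call_dmrs(d, cfg)
  r2 <- call_dmrs(shuffled, cfg)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$direction, c("hyper", "hypo"))
  expect_equal(nrow(r1), 2L)
})

test_that("DMR calling equals brute-force window enumeration", {
  set.seed(91)
  cfg_base <- comparison_config()
  for (rep_i in 1:6) {
    len <- 5000L
    n <- sample(c(15L, 40L, 80L), 1L)
    pos <- sort(sample.int(len - 10L, n)) + 5L
    pos <- unique(pos)
    dmcs <- make_dmcs(pos)
    for (md in c(1L, 5L, 10L)) {
      cfg <- comparison_config(min_dmcs = md)
      got <- call_dmrs(dmcs, cfg)
      want <- oracle_dmrs(pos, len, min_dmcs = md)
      expect_equal(got[, .(start, end, n_dmcs)],
                   want, ignore_attr = TRUE,
                   info = sprintf("rep %d min_dmcs %d", rep_i, md))
    }
  }
})

test_that("raising min_dmcs only shrinks regions (nesting, fewer member DMCs)", {
  set.seed(17)
  pos <- sort(sample.int(4000L, 120L))
  dmcs <- make_dmcs(unique(pos))
  res <- lapply(1:15, function(md)
    call_dmrs(dmcs, comparison_config(min_dmcs = md)))
  totals <- vapply(res, function(r) sum(r$n_dmcs), integer(1L))
  expect_true(all(diff(totals) <= 0L))
  # every region at a stricter threshold nests inside one at a looser one
  for (i in 2:15) {
    hi <- res[[i]]; lo <- res[[i - 1L]]
    if (!nrow(hi)) next
    for (j in seq_len(nrow(hi))) {
      expect_true(any(lo$start <= hi$start[j] & lo$end >= hi$end[j]),
                  info = sprintf("min_dmcs %d region %d", i, j))
    }
  }
})

test_that("DMC composition fractions sum to one", {
  d <- rbind(make_dmcs(c(10L, 20L, 30L), "hyper", "CHH"),
             make_dmcs(40L, "hypo", "CG"))
  comp <- dmc_composition(d)
  expect_equal(comp[context == "CHH" & direction == "hyper", fraction], 0.75)
  expect_equal(comp[context == "CG" & direction == "hypo", fraction], 0.25)
  expect_equal(sum(comp$fraction), 1)
  empty <- dmc_composition(d[0])
  expect_true(all(empty$n == 0L))
  expect_true(all(empty$fraction == 0))
  solo <- dmc_composition(make_dmcs(1:5 * 10L))
  expect_equal(solo[context == "CHH" & direction == "hyper", fraction], 1)
})
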