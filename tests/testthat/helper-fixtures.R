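# Deterministic six-gene promoter fixture with designed bin patterns.
# Baseline CHH level 0.10 at every promoter site in both stages; the ripe
# stage adds the designed per-bin differences. Coverage 100 everywhere makes
# every bin level exact.
responsive_fixture <- function() {
  genes <- data.table(
    gene_id = paste0("g", 1:6),
    chrom = "chrR",
    start = c(10000L, 18000L, 26000L, 34000L, 42000L, 50000L),
    end = c(10999L, 18999L, 26999L, 34999L, 42999L, 50999L),
    strand = c("+", "+", "+", "+", "+", "-"))
  genes[, id := gene_id]
  # designed differences per (gene, bin): >= 2 bins beyond +/-0.05 makes a
  # gene responsive in that direction
  design <- rbind(
    data.table(gene_id = "g1", bin = c(1L, 2L), diff = 0.06),   # hyper
    data.table(gene_id = "g2", bin = 5L, diff = 0.20),          # single bin
    data.table(gene_id = "g3", bin = c(3L, 7L), diff = c(0.06, -0.06)),
    data.table(gene_id = "g4", bin = c(3L, 4L, 5L), diff = -0.08), # hypo
    data.table(gene_id = "g6", bin = c(1L, 2L), diff = 0.10))   # minus strand
  truth <- data.table(
    gene_id = paste0("g", 1:6),
    hyper = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    hypo = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))

  # promoter bin interval in genome coordinates
  bin_interval <- function(g, b) {
    if (g$strand == "+") {
      c(g$start - b * 100L, g$start - (b - 1L) * 100L - 1L)
    } else {
      c(g$end + (b - 1L) * 100L + 1L, g$end + b * 100L)
    }
  }
  sites <- rbindlist(lapply(1:6, function(i) {
    g <- genes[i]
    rbindlist(lapply(1:20, function(b) {
      iv <- bin_interval(g, b)
      pos <- seq.int(iv[1L] + 4L, iv[2L] - 4L, by = 10L)
      data.table(gene_id = g$gene_id, bin = b, pos = pos)
    }))
  }))
  sites <- merge(sites, design, by = c("gene_id", "bin"), all.x = TRUE)
  sites[is.na(diff), diff := 0]
  base <- 0.10
  mk <- function(level_vec, stage) {
    methylome(data.table(chrom = "chrR", pos = sites$pos, strand = "+",
                         n_meth = as.integer(round(level_vec * 100)),
                         n_unmeth = 100L -
                           as.integer(round(level_vec * 100)),
                         subcontext = "CAA"),
              sample_id = paste0("fix_", stage), tissue = "pulp",
              stage = stage)
  }
  list(genes = genes,
       immature = list(mk(rep(base, nrow(sites)), "immature")),
       ripe = list(mk(base + sites$diff, "ripe")),
       truth = truth)
}
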