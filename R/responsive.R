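#' Promoter-bin methylation differences between two stages
#'
#' Divides the 2-kb promoter (strand-aware upstream of the TSS) of every
#' gene into 20 bins of 100 bp — bin 1 adjacent to the TSS, bin 20 most
#' distal — pools replicate counts per stage by summation, and reports the
#' coverage-weighted level per bin and stage plus the difference
#' (ripe - immature). A bin with zero coverage in either stage is undefined
#' (`NA` difference) and never counted as differential. Promoters running
#' off the sequence end are truncated and flagged.
#'
#' A bin is differentially methylated when its absolute difference exceeds
#' `diff_threshold` (default 0.05, the standard CHH cutoff), signed per
#' direction.
#'
#' @param genes An [annotation_set()] (its `genes` slot is used) or a
#'   `GRanges`/data.frame of gene intervals with `id` and strand.
#' @param immature,ripe Lists of [methylome()]s (replicates of each stage).
#' @param context Context to profile (default `"CHH"`).
#' @param diff_threshold Differential-bin threshold on `|difference|`.
#' @param n_bins,bin_size Promoter binning (defaults 20 x 100 bp).
#' @param window `"upstream"` (default; Methods-style 2-kb promoter) or
#'   `"tss"` for a window centred on the TSS (`n_bins` bins upstream plus
#'   `n_bins` downstream).
#' @return A `promoter_bin_profiles` list with `bins` (long data.table:
#'   `gene_id`, `bin` 1..n from the TSS outwards, negative bins downstream
#'   when `window = "tss"`, `level_immature`, `level_ripe`, `cov_immature`,
#'   `cov_ripe`, `difference`, `differential`, `diff_sign`) and `genes`
#'   (per-gene: `gene_id`, `strand`, `truncated`, `n_diff_bins_hyper`,
#'   `n_diff_bins_hypo`).
#' @export
promoter_bin_diffs <- function(genes, immature, ripe, context = "CHH",
                               diff_threshold = 0.05, n_bins = 20L,
                               bin_size = 100L,
                               window = c("upstream", "tss")) {
  window <- match.arg(window)
  gr <- if (inherits(genes, "annotation_set")) genes$genes else
    .as_granges(genes)
  if (!length(gr)) stop("no genes supplied")
  seqlens <- if (inherits(genes, "annotation_set")) genes$seqlengths else NULL
  g <- data.table(
    gene_id = as.character(gr$id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  g[strand == "*", strand := "+"]
  g[, tss := ifelse(strand == "+", start, end)]
  bins_idx <- if (window == "upstream") seq_len(n_bins) else
    c(seq_len(n_bins), -seq_len(n_bins))
  ## bin b (b > 0): strand-local upstream offsets ((b-1)*bin_size, b*bin_size]
  ## bin -b: downstream offsets, TSS included in bin -1
  grid <- g[, .(bin = bins_idx), by = .(gene_id, chrom, strand, tss)]
  grid[, `:=`(
    start = ifelse(strand == "+",
                   ifelse(bin > 0, tss - bin * bin_size,
                          tss + (-bin - 1L) * bin_size),
                   ifelse(bin > 0, tss + (bin - 1L) * bin_size + 1L,
                          tss - (-bin) * bin_size + 1L)),
    end = ifelse(strand == "+",
                 ifelse(bin > 0, tss - (bin - 1L) * bin_size - 1L,
                        tss + (-bin) * bin_size - 1L),
                 ifelse(bin > 0, tss + bin * bin_size,
                        tss - (-bin - 1L) * bin_size)))]
  ## truncate to sequence bounds
  grid[, truncated := start < 1L]
  grid[start < 1L, start := 1L]
  if (!is.null(seqlens)) {
    lens <- seqlens[grid$chrom]
    grid[end > lens, truncated := TRUE]
    grid[, end := pmin(end, lens)]
  }
  grid <- grid[start <= end | truncated]
  ctx_keep <- context
  pool_stage <- function(samples) {
    rbindlist(lapply(samples, function(s) {
      stopifnot(inherits(s, "methylome"))
      s$sites[context %in% ctx_keep,
              .(chrom, pos, m = as.numeric(n_meth),
                t = as.numeric(n_meth) + as.numeric(n_unmeth))]
    }))[, .(m = sum(m), t = sum(t)), by = .(chrom, pos)]
  }
  stage_bins <- function(sites_pooled) {
    s <- copy(sites_pooled)[, `:=`(s1 = pos, s2 = pos)]
    reg <- grid[start <= end, .(gene_id, bin, chrom, start, end)]
    setkey(reg, chrom, start, end)
    ov <- foverlaps(s, reg, by.x = c("chrom", "s1", "s2"),
                    by.y = c("chrom", "start", "end"), nomatch = NULL)
    ov[, .(m = sum(m), t = sum(t)), by = .(gene_id, bin)]
  }
  im <- stage_bins(pool_stage(immature))
  rp <- stage_bins(pool_stage(ripe))
  out <- grid[, .(gene_id, bin, chrom, start, end, strand, truncated)]
  out <- merge(out, im, by = c("gene_id", "bin"), all.x = TRUE)
  setnames(out, c("m", "t"), c("m_im", "cov_immature"))
  out <- merge(out, rp, by = c("gene_id", "bin"), all.x = TRUE)
  setnames(out, c("m", "t"), c("m_rp", "cov_ripe"))
  out[is.na(cov_immature), cov_immature := 0]
  out[is.na(cov_ripe), cov_ripe := 0]
  out[, `:=`(level_immature = ifelse(cov_immature > 0, m_im / cov_immature,
                                     NA_real_),
             level_ripe = ifelse(cov_ripe > 0, m_rp / cov_ripe, NA_real_))]
  out[, difference := level_ripe - level_immature]
  out[, differential := !is.na(difference) & abs(difference) > diff_threshold]
  out[, diff_sign := fifelse(differential & difference > 0, 1L,
                             fifelse(differential, -1L, 0L))]
  out[, c("m_im", "m_rp") := NULL]
  setorder(out, gene_id, bin)
  per_gene <- out[, .(strand = strand[1L], truncated = any(truncated),
                      n_diff_bins_hyper = sum(diff_sign == 1L),
                      n_diff_bins_hypo = sum(diff_sign == -1L)),
                  by = gene_id]
  n_trunc <- sum(per_gene$truncated)
  if (n_trunc) {
    message(n_trunc, " gene promoter(s) truncated at sequence bounds")
  }
  structure(list(bins = out[], genes = per_gene[], context = context,
                 diff_threshold = diff_threshold, window = window),
            class = "promoter_bin_profiles")
}

#' Call methylation-responsive genes from promoter-bin profiles
#'
#' A gene is methylation-responsive in a direction when at least
#' `min_diff_bins` (default 2) of its promoter bins are differentially
#' methylated in that direction. The gene-level methylation difference is
#' the mean of the differences of its differential bins (defined only when
#' at least one bin is differential).
#'
#' @param profiles A `promoter_bin_profiles` from [promoter_bin_diffs()].
#' @param min_diff_bins Minimum differential bins per direction (default 2).
#' @return A `responsive_calls` data.table: `gene_id`, `responsive_hyper`,
#'   `responsive_hypo`, `n_diff_bins_hyper`, `n_diff_bins_hypo`,
#'   `n_diff_bins`, `gene_mchh_difference`.
#' @export
call_responsive_genes <- function(profiles, min_diff_bins = 2L) {
  stopifnot(inherits(profiles, "promoter_bin_profiles"))
  gene_diff <- profiles$bins[differential == TRUE,
                             .(gene_mchh_difference = mean(difference),
                               n_diff_bins = .N),
                             by = gene_id]
  out <- merge(profiles$genes[, .(gene_id, n_diff_bins_hyper,
                                  n_diff_bins_hypo)],
               gene_diff, by = "gene_id", all.x = TRUE)
  out[is.na(n_diff_bins), n_diff_bins := 0L]
  out[, `:=`(responsive_hyper = n_diff_bins_hyper >= min_diff_bins,
             responsive_hypo = n_diff_bins_hypo >= min_diff_bins)]
  setcolorder(out, c("gene_id", "responsive_hyper", "responsive_hypo",
                     "n_diff_bins_hyper", "n_diff_bins_hypo", "n_diff_bins",
                     "gene_mchh_difference"))
  setattr(out, "class", c("responsive_calls", class(out)))
  out[]
}

#' Cross-tissue categories of promoter-hypermethylated genes
#'
#' Crosses the `responsive_hyper` flags of the two tissues' ripening
#' comparisons: hypermethylated only in pulp (`pulp_specific`), in both
#' (`common`), only in skin (`skin_specific`), or `none`.
#'
#' @param pulp_calls,skin_calls `responsive_calls` tables for the two
#'   tissues. Genes present in only one set are treated as non-responsive in
#'   the other (with a warning).
#' @return data.table (`gene_id`, `category`).
#' @export
classify_gene_tissue_specificity <- function(pulp_calls, skin_calls) {
  p <- as.data.table(pulp_calls)[, .(gene_id, hyper_pulp = responsive_hyper)]
  s <- as.data.table(skin_calls)[, .(gene_id, hyper_skin = responsive_hyper)]
  only <- c(setdiff(p$gene_id, s$gene_id), setdiff(s$gene_id, p$gene_id))
  if (length(only)) {
    warning(length(only), " gene(s) present in one call set only; ",
            "treated as non-responsive there")
  }
  m <- merge(p, s, by = "gene_id", all = TRUE)
  m[is.na(hyper_pulp), hyper_pulp := FALSE]
  m[is.na(hyper_skin), hyper_skin := FALSE]
  m[, category := fifelse(hyper_pulp & hyper_skin, "common",
                   fifelse(hyper_pulp, "pulp_specific",
                    fifelse(hyper_skin, "skin_specific", "none")))]
  m[, .(gene_id, category)]
}

#' Read a differential-expression table
#'
#' TSV with header and columns `gene_id`, `tissue`, `fpkm_immature`,
#' `fpkm_ripe`, `de_direction` (`up`/`down`/`none`, from an external DE
#' analysis — DE calling itself is out of scope here and deliberately not
#' re-implemented).
#'
#' @param path TSV path.
#' @return data.table of expression records.
#' @export
read_expression_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  required <- c("gene_id", "tissue", "fpkm_immature", "fpkm_ripe",
                "de_direction")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("expression table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(dt$de_direction), c("up", "down", "none"))
  if (length(bad)) stop("invalid de_direction value(s): ",
                        paste(bad, collapse = ", "))
  dt[]
}

#' Cross-tabulate hypermethylation categories with tissue-restricted DE
#'
#' For pulp-specific hypermethylated genes, counts those differentially
#' expressed only in pulp (split up/down); for skin-specific genes, those DE
#' only in skin; for common genes, those DE in both tissues (up/down when
#' concordant, `mixed` otherwise). Genes absent from the expression table
#' count as not differentially expressed.
#'
#' @param categories data.table (`gene_id`, `category`) from
#'   [classify_gene_tissue_specificity()].
#' @param expression Expression records ([read_expression_table()] format),
#'   one row per gene x tissue.
#' @return List with `counts` (data.table `category`, `de_pattern`, `n`) and
#'   `genes` (per-gene table with `de_pulp`, `de_skin`, `de_pattern`).
#' @export
integrate_expression <- function(categories, expression) {
  cat_dt <- as.data.table(categories)
  expr <- as.data.table(expression)
  de <- dcast(expr[, .(gene_id, tissue, de_direction)],
              gene_id ~ tissue, value.var = "de_direction")
  for (col in c("pulp", "skin")) {
    if (!col %in% names(de)) de[, (col) := "none"]
  }
  setnames(de, c("pulp", "skin"), c("de_pulp", "de_skin"))
  m <- merge(cat_dt, de[, .(gene_id, de_pulp, de_skin)],
             by = "gene_id", all.x = TRUE)
  n_missing <- sum(is.na(m$de_pulp) & is.na(m$de_skin))
  if (n_missing) {
    warning(n_missing, " gene(s) missing from the expression table; ",
            "counted as not differentially expressed")
  }
  m[is.na(de_pulp), de_pulp := "none"]
  m[is.na(de_skin), de_skin := "none"]
  m[, de_pattern := fcase(
    category == "pulp_specific" & de_pulp != "none" & de_skin == "none",
    de_pulp,
    category == "skin_specific" & de_skin != "none" & de_pulp == "none",
    de_skin,
    category == "common" & de_pulp != "none" & de_skin != "none" &
      de_pulp == de_skin, de_pulp,
    category == "common" & de_pulp != "none" & de_skin != "none", "mixed",
    default = "excluded")]
  counts <- CJ(category = c("pulp_specific", "common", "skin_specific"),
               de_pattern = c("up", "down"))
  tab <- m[de_pattern %in% c("up", "down", "mixed"),
           .(n = .N), by = .(category, de_pattern)]
  counts <- tab[counts, on = c("category", "de_pattern")]
  counts[is.na(n), n := 0L]
  mixed <- m[de_pattern == "mixed", .(n = .N), by = .(category)]
  if (nrow(mixed)) {
    counts <- rbind(counts, mixed[, .(category, de_pattern = "mixed", n)])
  }
  list(counts = counts[], genes = m[])
}

#' Methylation of active versus inactive genes
#'
#' Splits genes by expression at the methylome's stage/tissue (active:
#' abundance >= `fpkm_threshold`; inactive otherwise) and compares their
#' promoter (2-kb upstream) and gene-body coverage-weighted methylation
#' levels per context with the two-sided Wilcoxon rank-sum test.
#'
#' @param expression Expression records (the rows matching the methylome's
#'   tissue are used; the stage column matching the methylome's stage, i.e.
#'   `fpkm_immature` or `fpkm_ripe`).
#' @param genes An [annotation_set()] or gene intervals.
#' @param x A [methylome()] with `tissue` and `stage` metadata.
#' @param fpkm_threshold Activity threshold (default 1).
#' @param promoter_width Upstream promoter width (default 2000 bp).
#' @return List with `levels` (per gene x region_type x context) and `tests`
#'   (`region_type`, `context`, `n_active`, `n_inactive`, `median_active`,
#'   `median_inactive`, `p_value`); tests are `NA` when a group is empty.
#' @export
active_inactive_summary <- function(expression, genes, x,
                                    fpkm_threshold = 1,
                                    promoter_width = 2000L) {
  stopifnot(inherits(x, "methylome"))
  gr <- if (inherits(genes, "annotation_set")) genes$genes else
    .as_granges(genes)
  expr <- as.data.table(expression)
  if (!is.na(x$tissue) && "tissue" %in% names(expr) &&
      x$tissue %in% expr$tissue) {
    expr <- expr[tissue == x$tissue]
  }
  fpkm_col <- if (identical(x$stage, "ripe")) "fpkm_ripe" else "fpkm_immature"
  act <- expr[, .(gene_id, active = get(fpkm_col) >= fpkm_threshold)]
  g <- data.table(
    gene_id = as.character(gr$id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  g[strand == "*", strand := "+"]
  body <- g[, .(gene_id, chrom, start, end, region_type = "body")]
  prom <- g[, .(gene_id, chrom,
                start = ifelse(strand == "+",
                               pmax(1L, start - promoter_width), end + 1L),
                end = ifelse(strand == "+", start - 1L,
                             end + promoter_width),
                region_type = "promoter")]
  prom <- prom[start <= end]
  regs <- rbind(body, prom)
  lv <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx) {
    out <- region_levels(x, regs[, .(chrom, start, end,
                                     region_id = paste(gene_id, region_type,
                                                       sep = "|"))],
                         context = ctx)
    out[, context := ctx]
    out
  }))
  lv[, c("gene_id", "region_type") := tstrsplit(region_id, "|", fixed = TRUE)]
  lv <- merge(lv, act, by = "gene_id")
  tests <- lv[!is.na(level), {
    a <- level[active == TRUE]; b <- level[active == FALSE]
    if (length(a) && length(b)) {
      wt <- wilcoxon_rank_sum(a, b)
      .(n_active = length(a), n_inactive = length(b),
        median_active = stats::median(a), median_inactive = stats::median(b),
        p_value = wt$p_value, signif_code = wt$signif_code)
    } else .(n_active = length(a), n_inactive = length(b),
             median_active = NA_real_, median_inactive = NA_real_,
             p_value = NA_real_, signif_code = NA_character_)
  }, by = .(region_type, context)]
  list(levels = lv[], tests = tests[])
}
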