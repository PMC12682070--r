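#' Classify ripening-induced DMRs by tissue specificity
#'
#' Given the same-context, same-direction DMR sets of two tissues (here pulp
#' and skin), assigns every region to one of three groups: regions private
#' to the first tissue (`pulp_specific`, Group 1), regions overlapping by at
#' least 1 bp with a region of the other tissue (`common`, Group 2, reported
#' once as the union interval of the overlapping regions), and regions
#' private to the second tissue (`skin_specific`, Group 3).
#'
#' @param pulp_dmrs,skin_dmrs `dmr_regions` tables (or data.frames with
#'   `chrom`, `start`, `end`, `context`, `direction`) from the two tissues'
#'   ripening comparisons; both must share a single context and direction.
#' @return List with `assignments` (one row per input region: `tissue`,
#'   `chrom`, `start`, `end`, `group`, `common_id` linking into the collapsed
#'   table or `NA`) and `common_regions` (collapsed union intervals:
#'   `common_id`, `chrom`, `start`, `end`, `n_pulp`, `n_skin`).
#' @export
classify_dmr_groups <- function(pulp_dmrs, skin_dmrs) {
  pd <- as.data.table(pulp_dmrs)
  sd_ <- as.data.table(skin_dmrs)
  ctx <- unique(c(pd$context, sd_$context))
  dir <- unique(c(pd$direction, sd_$direction))
  if (length(ctx) > 1L || length(dir) > 1L) {
    stop("inputs mix contexts (", paste(ctx, collapse = ","),
         ") or directions (", paste(dir, collapse = ",") , ")")
  }
  gr <- function(d) if (nrow(d)) GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start, d$end)) else GenomicRanges::GRanges()
  pg <- gr(pd); sg <- gr(sd_)
  ov <- GenomicRanges::findOverlaps(pg, sg, minoverlap = 1L)
  p_common <- unique(S4Vectors::queryHits(ov))
  s_common <- unique(S4Vectors::subjectHits(ov))
  ## collapse each connected overlap component to its union interval;
  ## reduce() merges through chains because connectivity here is by overlap
  common_union <- GenomicRanges::reduce(c(pg[p_common], sg[s_common]))
  cu <- data.table(
    common_id = seq_along(common_union),
    chrom = as.character(GenomeInfoDb::seqnames(common_union)),
    start = BiocGenerics::start(common_union),
    end = BiocGenerics::end(common_union))
  link <- function(g, idx) {
    id <- rep(NA_integer_, length(g))
    if (length(idx) && length(common_union)) {
      h <- GenomicRanges::findOverlaps(g[idx], common_union)
      id[idx[S4Vectors::queryHits(h)]] <- S4Vectors::subjectHits(h)
    }
    id
  }
  p_id <- link(pg, p_common); s_id <- link(sg, s_common)
  asn <- rbind(
    data.table(tissue = "pulp", chrom = pd$chrom, start = pd$start,
               end = pd$end,
               group = ifelse(is.na(p_id), "pulp_specific", "common"),
               common_id = p_id),
    data.table(tissue = "skin", chrom = sd_$chrom, start = sd_$start,
               end = sd_$end,
               group = ifelse(is.na(s_id), "skin_specific", "common"),
               common_id = s_id))
  if (length(common_union)) {
    cu[, n_pulp := tabulate(p_id[!is.na(p_id)], nbins = .N)]
    cu[, n_skin := tabulate(s_id[!is.na(s_id)], nbins = .N)]
  } else {
    cu[, `:=`(n_pulp = integer(), n_skin = integer())]
  }
  list(assignments = asn[], common_regions = cu[],
       context = if (length(ctx)) ctx else NA_character_,
       direction = if (length(dir)) dir else NA_character_)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution when the combined sample size is at most 20 and there
#' are no ties; normal approximation with tie and continuity correction
#' otherwise. Significance is coded in the figure convention: `***` for
#' p < 0.001, `NS` otherwise.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param exact_max Combined-n limit for the exact distribution (default 20).
#' @return List with `p_value`, `statistic` (rank-sum W of the first
#'   sample), `exact` (logical), `signif_code`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b, exact_max = 20L) {
  if (!length(values_a) || !length(values_b)) {
    stop("both samples must be non-empty")
  }
  if (length(unique(c(values_a, values_b))) == 1L) {
    ## fully tied: the test carries no information
    return(list(p_value = 1, statistic = length(values_a) *
                  length(values_b) / 2, exact = FALSE, signif_code = "NS"))
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- (length(values_a) + length(values_b)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       exact = use_exact,
       signif_code = if (wt$p.value < 0.001) "***" else "NS")
}

#' Coverage-weighted methylation level of regions in a methylome
#'
#' @param x A [methylome()].
#' @param regions data.frame/data.table with `chrom`, `start`, `end`
#'   (1-based closed) and optionally `region_id`.
#' @param context Context to restrict to (default `"CHH"`); `NULL` for all.
#' @return data.table (`region_id`, `chrom`, `start`, `end`, `level`,
#'   `coverage`, `n_sites`); regions without covered sites get `NA` level.
#' @export
region_levels <- function(x, regions, context = "CHH") {
  stopifnot(inherits(x, "methylome"))
  reg <- as.data.table(regions)[, .(chrom, start, end)]
  reg[, region_id := if ("region_id" %in% names(regions))
    regions$region_id else .I]
  ctx_keep <- context
  s <- x$sites
  if (!is.null(ctx_keep)) s <- s[context %in% ctx_keep]
  s <- s[, .(chrom, pos, n_meth, n_unmeth)]
  s[, `:=`(s1 = pos, s2 = pos)]
  setkey(reg, chrom, start, end)
  ov <- foverlaps(s, reg, by.x = c("chrom", "s1", "s2"),
                  by.y = c("chrom", "start", "end"), nomatch = NULL)
  agg <- ov[, .(level = sum(as.numeric(n_meth)) /
                  sum(as.numeric(n_meth) + as.numeric(n_unmeth)),
                coverage = sum(as.numeric(n_meth) + as.numeric(n_unmeth)),
                n_sites = .N),
            by = .(region_id, chrom, start, end)]
  out <- agg[reg, on = c("region_id", "chrom", "start", "end")]
  out[is.na(n_sites), `:=`(n_sites = 0L, coverage = 0)]
  setorder(out, chrom, start)
  setcolorder(out, c("region_id", "chrom", "start", "end", "level",
                     "coverage", "n_sites"))
  out[]
}

#' Per-group region-level methylation distributions and inter-tissue tests
#'
#' For each DMR group, computes the coverage-weighted CHH level of every
#' region in every supplied methylome (tissue x stage), then compares pulp
#' against skin within each (group, stage) with the two-sided Wilcoxon
#' rank-sum test — the contrast that reveals pre-existing inter-tissue
#' differences at the immature stage.
#'
#' @param assignments Result of [classify_dmr_groups()].
#' @param methylomes List of [methylome()]s with `tissue` and `stage`
#'   metadata set.
#' @param context Context (default `"CHH"`).
#' @return List with `levels` (long table: `group`, `region_id`, `chrom`,
#'   `start`, `end`, `tissue`, `stage`, `level`, ...) and `tests`
#'   (`group`, `stage`, `n_pulp`, `n_skin`, `p_value`, `signif_code`).
#' @export
group_level_compare <- function(assignments, methylomes, context = "CHH") {
  asn <- assignments$assignments
  ## one interval per assignment unit: specific regions as-is, common
  ## regions via their collapsed unions (each counted once)
  reg <- rbind(
    asn[group != "common", .(group, chrom, start, end)],
    assignments$common_regions[, .(group = "common", chrom, start, end)])
  if (!nrow(reg)) stop("no regions to compare")
  reg[, region_id := .I]
  lv <- rbindlist(lapply(methylomes, function(m) {
    out <- region_levels(m, reg, context = context)
    out[, `:=`(tissue = m$tissue, stage = m$stage, replicate = m$replicate)]
    out
  }))
  lv <- merge(lv, reg[, .(region_id, group)], by = "region_id")
  ## average replicate levels per region/tissue/stage (regions uncovered in
  ## a sample drop out of that sample only)
  per <- lv[!is.na(level),
            .(level = sum(level * coverage) / sum(coverage)),
            by = .(group, region_id, chrom, start, end, tissue, stage)]
  tests <- per[, {
    a <- level[tissue == "pulp"]
    b <- level[tissue == "skin"]
    if (length(a) && length(b)) {
      wt <- wilcoxon_rank_sum(a, b)
      .(n_pulp = length(a), n_skin = length(b), p_value = wt$p_value,
        signif_code = wt$signif_code)
    } else .(n_pulp = length(a), n_skin = length(b), p_value = NA_real_,
             signif_code = NA_character_)
  }, by = .(group, stage)]
  list(levels = per[], tests = tests[])
}
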