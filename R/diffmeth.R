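#' Comparison configuration for DMC/DMR calling
#'
#' Defaults follow the standard plant WGBS practice used here: minimum
#' absolute level differences of 0.20 (CG), 0.10 (CHG), 0.05 (CHH); raw
#' p-value cutoff 0.05 (no multiple-testing correction by default, matching
#' the stated per-site procedure; set `use_qvalue = TRUE` for BH-adjusted
#' calling); DMRs from 200-bp windows advanced by 50 bp, candidate regions
#' merged when separated by at most 100 bp and retained when holding at
#' least 10 DMCs; per-sample validity depth 4.
#'
#' @param diff_thresholds Named numeric, minimum `|difference|` per context.
#' @param p_threshold P-value cutoff for DMCs.
#' @param window,step Sliding-window width and step (bp), `step <= window`.
#' @param merge_gap Maximum gap (bp) between candidate regions to merge.
#' @param min_dmcs Minimum DMC count for a merged region to be kept.
#' @param min_depth Per-sample minimum site depth.
#' @param use_qvalue If `TRUE`, threshold BH-adjusted p-values instead.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(diff_thresholds = c(CG = 0.20, CHG = 0.10,
                                                  CHH = 0.05),
                              p_threshold = 0.05, window = 200L, step = 50L,
                              merge_gap = 100L, min_dmcs = 10L,
                              min_depth = 4L, use_qvalue = FALSE) {
  stopifnot(all(c("CG", "CHG", "CHH") %in% names(diff_thresholds)),
            all(diff_thresholds > 0), p_threshold > 0, window > 0,
            step > 0, step <= window, merge_gap >= 0, min_dmcs >= 1,
            min_depth >= 0)
  structure(list(diff_thresholds = diff_thresholds,
                 p_threshold = p_threshold, window = as.integer(window),
                 step = as.integer(step), merge_gap = as.integer(merge_gap),
                 min_dmcs = as.integer(min_dmcs),
                 min_depth = as.integer(min_depth), use_qvalue = use_qvalue),
            class = "comparison_config")
}

## Vectorised binomial log-likelihood at the MLE, with 0*log(0) = 0.
.ll_binom_mle <- function(m, t) {
  m <- as.numeric(m); t <- as.numeric(t)
  p <- m / t
  ifelse(m > 0, m * log(p), 0) + ifelse(t - m > 0, (t - m) * log1p(-p), 0)
}

#' Per-site two-group binomial likelihood-ratio test
#'
#' The DMC test: replicate counts are pooled within each group (the pooled
#' proportions are the closed-form MLEs of a binomial model with a group
#' indicator, i.e. the likelihood-ratio counterpart of a per-site logistic
#' regression on group). The statistic `2*(ll_alt - ll_null)` is referred to
#' a chi-square distribution with 1 df. The reported difference is
#' `pooled level(b) - pooled level(a)`.
#'
#' @param group_a,group_b Lists (or 2-column matrices) of per-replicate
#'   `(n_meth, n_total)` pairs; every replicate total must be positive.
#' @return List with `difference`, `statistic`, `p_value`, and the pooled
#'   `level_a`, `level_b`.
#' @examples
#' lrt_site_test(list(c(2, 20), c(3, 20)), list(c(10, 20), c(12, 20)))
#' @export
lrt_site_test <- function(group_a, group_b) {
  pool <- function(g) {
    m <- if (is.matrix(g)) g else do.call(rbind, g)
    if (!length(m)) stop("empty replicate group")
    if (any(m[, 2L] <= 0)) stop("every replicate total must be > 0")
    if (any(m[, 1L] < 0) || any(m[, 1L] > m[, 2L]))
      stop("methylated count must lie in [0, total]")
    colSums(m)
  }
  a <- pool(group_a); b <- pool(group_b)
  res <- lrt_pooled(a[1L], a[2L], b[1L], b[2L])
  list(difference = res$difference, statistic = res$statistic,
       p_value = res$p_value, level_a = a[1L] / a[2L], level_b = b[1L] / b[2L])
}

#' Vectorised pooled-count binomial LRT
#'
#' Workhorse behind [lrt_site_test()] and [call_dmcs()]: takes pooled counts
#' per group and returns the chi-square(1) likelihood-ratio test.
#'
#' @param m_a,t_a,m_b,t_b Numeric vectors of pooled methylated and total
#'   counts for groups a and b (all totals > 0).
#' @return data.table (`difference`, `statistic`, `p_value`).
#' @export
lrt_pooled <- function(m_a, t_a, m_b, t_b) {
  stopifnot(all(t_a > 0), all(t_b > 0))
  stat <- 2 * (.ll_binom_mle(m_a, t_a) + .ll_binom_mle(m_b, t_b) -
                 .ll_binom_mle(m_a + m_b, t_a + t_b))
  stat <- pmax(stat, 0)   # guard tiny negative rounding
  data.table(difference = m_b / t_b - m_a / t_a, statistic = stat,
             p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Call differentially methylated cytosines between two sample groups
#'
#' The site universe of a comparison is the intersection of valid sites:
#' positions with depth at least `config$min_depth` in every replicate of
#' both groups. Counts are pooled per group, tested with [lrt_pooled()], and
#' a call is emitted only when both the context-specific absolute difference
#' threshold and the p-value cutoff are met. Direction is `hyper` when group
#' b exceeds group a.
#'
#' @param group_a,group_b Lists of [methylome()]s (the replicates of each
#'   group; a comparison is b relative to a, e.g. ripe vs immature).
#' @param config A [comparison_config()].
#' @param exclude_chrom Sequences to exclude (e.g. the chloroplast).
#' @return A `dmc_calls` data.table: `chrom`, `pos`, `strand`, `context`,
#'   `level_a`, `level_b`, `difference`, `statistic`, `p_value`, `t_a`,
#'   `t_b`, `direction`.
#' @export
call_dmcs <- function(group_a, group_b, config = comparison_config(),
                      exclude_chrom = character()) {
  stopifnot(inherits(config, "comparison_config"),
            length(group_a) >= 1L, length(group_b) >= 1L)
  groups <- list(a = group_a, b = group_b)
  n_rep <- vapply(groups, length, integer(1L))
  pooled <- lapply(names(groups), function(g) {
    reps <- rbindlist(lapply(groups[[g]], function(s) {
      stopifnot(inherits(s, "methylome"))
      s$sites[!chrom %in% exclude_chrom &
                n_meth + n_unmeth >= config$min_depth,
              .(chrom, pos, strand, context,
                m = as.numeric(n_meth),
                t = as.numeric(n_meth) + as.numeric(n_unmeth))]
    }))
    ## keep only sites valid in every replicate of this group
    reps[, if (.N == n_rep[[g]])
      .(context = context[1L], m = sum(m), t = sum(t)),
      by = .(chrom, pos, strand)]
  })
  shared <- merge(pooled[[1L]], pooled[[2L]],
                  by = c("chrom", "pos", "strand"), suffixes = c("_a", "_b"))
  if (!nrow(shared)) {
    warning("no sites shared by all replicates of both groups")
    return(.empty_dmc_table())
  }
  res <- lrt_pooled(shared$m_a, shared$t_a, shared$m_b, shared$t_b)
  shared[, `:=`(level_a = m_a / t_a, level_b = m_b / t_b,
                difference = res$difference, statistic = res$statistic,
                p_value = res$p_value)]
  shared[, p_eff := if (config$use_qvalue)
    stats::p.adjust(p_value, "BH") else p_value]
  thr <- config$diff_thresholds[shared$context_a]
  calls <- shared[abs(difference) > thr & p_eff < config$p_threshold]
  out <- calls[, .(chrom, pos, strand, context = context_a, level_a, level_b,
                   difference, statistic, p_value, t_a, t_b,
                   direction = ifelse(difference > 0, "hyper", "hypo"))]
  setkeyv(out, c("chrom", "pos", "strand"))
  setattr(out, "class", c("dmc_calls", class(out)))
  out[]
}

.empty_dmc_table <- function() {
  out <- data.table(chrom = character(), pos = integer(), strand = character(),
                    context = character(), level_a = numeric(),
                    level_b = numeric(), difference = numeric(),
                    statistic = numeric(), p_value = numeric(),
                    t_a = numeric(), t_b = numeric(), direction = character())
  setattr(out, "class", c("dmc_calls", class(out)))
  out
}

#' Build differentially methylated regions from DMC calls
#'
#' Per context and direction: 200-bp windows advanced by 50 bp along each
#' sequence; a window is a candidate when it contains at least `min_dmcs`
#' matching DMCs (the density requirement that separates genuine regional
#' shifts from the scattered per-site false positives an uncorrected
#' p < 0.05 test necessarily leaves); overlapping candidate windows are
#' unioned, unions separated by at most `merge_gap` bp are merged, merged
#' regions failing the `min_dmcs` count are dropped (implied by
#' construction), and each region is trimmed to its outermost member DMC
#' positions. Hyper and hypo regions are built separately and never merged
#' together.
#'
#' @param dmcs A `dmc_calls` table from a single comparison.
#' @param config A [comparison_config()].
#' @return A `dmr_regions` data.table: `chrom`, `start`, `end` (1-based
#'   closed), `context`, `direction`, `n_dmcs`, `mean_difference`
#'   (coverage-weighted over member DMCs), `width`.
#' @export
call_dmrs <- function(dmcs, config = comparison_config()) {
  stopifnot(inherits(config, "comparison_config"))
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      n_dmcs = integer(), mean_difference = numeric(),
                      width = integer())
  if (!nrow(dmcs)) {
    setattr(empty, "class", c("dmr_regions", class(empty)))
    return(empty)
  }
  w <- config$window; st <- config$step
  dt <- as.data.table(dmcs)[order(chrom, pos, strand)]
  out <- dt[, {
    p <- pos
    ## windows start at 1 + k*step, k >= 0, width `w`; enumerate the (DMC,
    ## covering-window) pairs and keep windows dense enough in DMCs
    k_min <- pmax(0, ceiling((p - w) / st))
    k_max <- floor((p - 1) / st)
    ks <- unlist(Map(seq.int, k_min, k_max))
    win_counts <- data.table(k = ks)[, .N, by = k]
    cand_k <- win_counts[N >= config$min_dmcs, k]
    if (length(cand_k)) {
      cand <- IRanges::IRanges(start = 1L + cand_k * st,
                               end = cand_k * st + w)
      merged <- IRanges::reduce(cand, min.gapwidth = config$merge_gap + 1L)
      ov <- IRanges::findOverlaps(IRanges::IRanges(p, p), merged)
      dd <- data.table(pos = p[S4Vectors::queryHits(ov)],
                       diff = difference[S4Vectors::queryHits(ov)],
                       cov = as.numeric(t_a + t_b)[S4Vectors::queryHits(ov)],
                       region = S4Vectors::subjectHits(ov))
      reg <- dd[, .(start = min(pos), end = max(pos), n_dmcs = .N,
                    mean_difference = sum(diff * cov) / sum(cov)),
                by = region]
      reg[n_dmcs >= config$min_dmcs,
          .(start, end, n_dmcs, mean_difference)]
    } else {
      data.table(start = integer(), end = integer(), n_dmcs = integer(),
                 mean_difference = numeric())
    }
  }, by = .(chrom, context, direction)]
  if (!nrow(out)) {
    setattr(empty, "class", c("dmr_regions", class(empty)))
    return(empty)
  }
  out[, width := end - start + 1L]
  setcolorder(out, c("chrom", "start", "end", "context", "direction",
                     "n_dmcs", "mean_difference", "width"))
  setorder(out, chrom, start, context, direction)
  setattr(out, "class", c("dmr_regions", class(out)))
  out[]
}

#' DMC composition by context and direction
#'
#' @param dmcs A `dmc_calls` table.
#' @return data.table (`context`, `direction`, `n`, `fraction`) over all six
#'   context-by-direction cells; fractions sum to 1 (all zero on empty input).
#' @export
dmc_composition <- function(dmcs) {
  grid <- CJ(context = c("CG", "CHG", "CHH"),
             direction = c("hyper", "hypo"))
  if (!nrow(dmcs)) {
    grid[, `:=`(n = 0L, fraction = 0)]
    return(grid[])
  }
  counts <- as.data.table(dmcs)[, .(n = .N), by = .(context, direction)]
  out <- counts[grid, on = c("context", "direction")]
  out[is.na(n), n := 0L]
  out[, fraction := n / sum(n)]
  out[]
}
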