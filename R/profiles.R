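#' Genome-wide methylation levels per context
#'
#' Reports, for each sequence context, both the coverage-weighted level
#' (sum of methylated counts over sum of total counts — the level used
#' throughout this package) and the unweighted mean of per-site levels,
#' plus an all-context aggregate row (`context == "all"`).
#'
#' @param x A [methylome()].
#' @param exclude_chrom Sequences to drop first (e.g. the chloroplast, which
#'   reflects conversion error, not methylation). Default none.
#' @return A data.table with columns `context`, `n_sites`, `weighted_level`,
#'   `mean_site_level`. Contexts absent from the sample are reported with
#'   `n_sites = 0` and `NA` levels.
#' @export
global_levels <- function(x, exclude_chrom = character()) {
  stopifnot(inherits(x, "methylome"))
  s <- x$sites[!chrom %in% exclude_chrom]
  if (!nrow(s)) stop("methylome has no sites")
  per <- s[, .(n_sites = .N,
               weighted_level = sum(as.numeric(n_meth)) /
                 sum(as.numeric(n_meth) + as.numeric(n_unmeth)),
               mean_site_level = mean(n_meth / (n_meth + n_unmeth))),
           by = context]
  missing_ctx <- setdiff(c("CG", "CHG", "CHH"), per$context)
  if (length(missing_ctx)) {
    per <- rbind(per, data.table(context = missing_ctx, n_sites = 0L,
                                 weighted_level = NA_real_,
                                 mean_site_level = NA_real_))
  }
  all_row <- s[, .(context = "all", n_sites = .N,
                   weighted_level = sum(as.numeric(n_meth)) /
                     sum(as.numeric(n_meth) + as.numeric(n_unmeth)),
                   mean_site_level = mean(n_meth / (n_meth + n_unmeth)))]
  out <- rbind(per[order(match(context, c("CG", "CHG", "CHH")))], all_row)
  out[]
}

#' Bin the genome and summarise methylation (and feature density) per bin
#'
#' Tiles every sequence with fixed-size bins (the final bin of a sequence may
#' be shorter) and reports per-bin coverage-weighted levels and site counts
#' per context, plus optional gene/TE base-pair density and accessibility
#' base-pair coverage.
#'
#' @param x A [methylome()].
#' @param bin_size Bin width in bp (>= 100). 1 kb is the usual scale for
#'   replicate correlation; 100 kb for chromosome-scale density tracks.
#' @param annotations Optional [annotation_set()]; adds `gene_density` and
#'   `te_density` columns (fraction of bin bp covered).
#' @param accessibility Optional `GRanges`; adds `accessibility` (fraction of
#'   bin bp covered by accessible intervals).
#' @param seqlengths Named lengths; defaults to `annotations$seqlengths`, or
#'   the maximal site position per sequence when no annotation is given.
#' @return A `bin_track`: data.table with `chrom`, `start`, `end` (1-based
#'   closed), and per context `level_<ctx>` / `n_<ctx>` columns; `bin_size`
#'   carried as an attribute. Bins with no covered sites have `NA` level.
#' @export
bin_genome <- function(x, bin_size = 1000L, annotations = NULL,
                       accessibility = NULL, seqlengths = NULL) {
  stopifnot(inherits(x, "methylome"), bin_size >= 100L)
  if (is.null(seqlengths)) {
    seqlengths <- if (!is.null(annotations)) annotations$seqlengths else
      vapply(split(x$sites$pos, x$sites$chrom), max, integer(1L))
  }
  bins <- rbindlist(lapply(names(seqlengths), function(ch) {
    len <- seqlengths[[ch]]
    starts <- seq.int(1L, len, by = bin_size)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + bin_size - 1L, len))
  }))
  s <- x$sites[chrom %in% names(seqlengths)]
  s[, bin := (pos - 1L) %/% bin_size]
  agg <- s[, .(m = sum(as.numeric(n_meth)),
               t = sum(as.numeric(n_meth) + as.numeric(n_unmeth)),
               n = .N),
           by = .(chrom, bin, context)]
  for (ctx in c("CG", "CHG", "CHH")) {
    a <- agg[context == ctx]
    a[, start := bin * bin_size + 1L]
    bins[a, on = c("chrom", "start"),
         paste0(c("level_", "n_", "cov_"), ctx) :=
           .(i.m / i.t, i.n, i.t)]
    lvl <- paste0("level_", ctx); nn <- paste0("n_", ctx); cv <- paste0("cov_", ctx)
    bins[is.na(get(nn)), (nn) := 0L]
    bins[is.na(get(cv)), (cv) := 0]
  }
  if (!is.null(annotations)) {
    bins[, gene_density := .bin_coverage_fraction(bins, annotations$genes)]
    bins[, te_density := .bin_coverage_fraction(bins, annotations$tes)]
  }
  if (!is.null(accessibility)) {
    bins[, accessibility := .bin_coverage_fraction(bins, accessibility)]
  }
  setattr(bins, "bin_size", as.integer(bin_size))
  setattr(bins, "class", c("bin_track", class(bins)))
  bins[]
}

## fraction of each bin's bases covered by the (reduced) feature set
.bin_coverage_fraction <- function(bins, features) {
  if (is.null(features) || !length(features)) return(rep(0, nrow(bins)))
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start, bins$end))
  red <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(bin_gr, red)
  covered <- numeric(nrow(bins))
  if (length(ov)) {
    qs <- S4Vectors::queryHits(ov)
    inter_w <- pmin(bins$end[qs], BiocGenerics::end(red)[S4Vectors::subjectHits(ov)]) -
      pmax(bins$start[qs], BiocGenerics::start(red)[S4Vectors::subjectHits(ov)]) + 1L
    add <- tapply(inter_w, qs, sum)
    covered[as.integer(names(add))] <- as.numeric(add)
  }
  covered / (bins$end - bins$start + 1L)
}

#' Pearson correlation of binned methylation between two tracks
#'
#' The reproducibility statistic for biological replicates: levels of one
#' context are compared over bins defined (covered) in both tracks.
#'
#' @param a,b `bin_track`s with identical binning.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @return List with `r` (Pearson) and `n_bins` used.
#' @export
replicate_correlation <- function(a, b, context = "CHH") {
  stopifnot(attr(a, "bin_size") == attr(b, "bin_size"))
  lvl <- paste0("level_", context)
  m <- merge(a[, .(chrom, start, la = get(lvl))],
             b[, .(chrom, start, lb = get(lvl))],
             by = c("chrom", "start"))
  m <- m[!is.na(la) & !is.na(lb)]
  if (nrow(m) < 3L) stop("fewer than 3 bins with defined levels in both tracks")
  list(r = cor(m$la, m$lb), n_bins = nrow(m))
}

#' Correlation of binned methylation with feature density
#'
#' Chromosome-scale association between methylation and gene density, TE
#' density or chromatin accessibility, as Pearson correlation over bins.
#'
#' @param track A `bin_track` built with the relevant density column.
#' @param context Context level column to use.
#' @param feature One of `"gene_density"`, `"te_density"`, `"accessibility"`.
#' @return List with `r` and `n_bins`.
#' @export
density_correlation <- function(track, context = "CHH",
                                feature = c("gene_density", "te_density",
                                            "accessibility")) {
  feature <- match.arg(feature)
  if (!feature %in% names(track)) stop("track lacks column ", feature)
  lvl <- paste0("level_", context)
  m <- track[!is.na(get(lvl))]
  if (nrow(m) < 3L) stop("fewer than 3 bins with defined levels")
  list(r = cor(m[[lvl]], m[[feature]]), n_bins = nrow(m))
}

## Assign sites to meta-profile bins for one feature set.
## Returns data.table (bin_index, context, m, t) aggregated.
## Bin layout: 1..flank_bins upstream (distal -> proximal), then body_bins,
## then flank_bins downstream; all strand-local.
.metagene_assign <- function(sites, features, flank, body_bins, flank_bin) {
  flank_bins <- as.integer(flank / flank_bin)
  feat <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(features)),
    start = BiocGenerics::start(features),
    end = BiocGenerics::end(features),
    strand = as.character(BiocGenerics::strand(features)))
  feat[strand == "*", strand := "+"]
  feat[, feature_id := .I]
  feat[, `:=`(wstart = start - flank, wend = end + flank)]
  s <- sites[, .(chrom, pos, context, n_meth, n_unmeth)]
  s[, `:=`(s1 = pos, s2 = pos)]
  setkey(feat, chrom, wstart, wend)
  ov <- foverlaps(s, feat, by.x = c("chrom", "s1", "s2"),
                  by.y = c("chrom", "wstart", "wend"), nomatch = NULL)
  if (!nrow(ov)) return(data.table(bin_index = integer(), context = character(),
                                   m = numeric(), t = numeric()))
  ## strand-local offset relative to the feature 5' end; body by fractional
  ## position so short features still distribute over all body bins
  width <- ov$end - ov$start + 1L
  plus <- ov$strand == "+"
  up_off <- ifelse(plus, ov$start - ov$pos, ov$pos - ov$end)   # >0 upstream
  dn_off <- ifelse(plus, ov$pos - ov$end, ov$start - ov$pos)   # >0 downstream
  in_body <- up_off <= 0L & dn_off <= 0L
  frac <- ifelse(plus, (ov$pos - ov$start) / width, (ov$end - ov$pos) / width)
  bin_index <- integer(nrow(ov))
  bin_index[in_body] <- flank_bins +
    pmin(floor(frac[in_body] * body_bins), body_bins - 1L) + 1L
  is_up <- up_off > 0L
  bin_index[is_up] <- flank_bins - ceiling(up_off[is_up] / flank_bin) + 1L
  is_dn <- dn_off > 0L
  bin_index[is_dn] <- flank_bins + body_bins +
    ceiling(dn_off[is_dn] / flank_bin)
  keep <- bin_index >= 1L & bin_index <= 2L * flank_bins + body_bins
  data.table(bin_index = bin_index[keep], context = ov$context[keep],
             m = as.numeric(ov$n_meth[keep]),
             t = as.numeric(ov$n_meth[keep] + ov$n_unmeth[keep]))
}

.profile_from_assignment <- function(asg, n_bins) {
  agg <- asg[, .(level = sum(m) / sum(t), coverage = sum(t), n_sites = .N),
             by = .(context, bin_index)]
  grid <- CJ(context = c("CG", "CHG", "CHH"), bin_index = seq_len(n_bins))
  out <- agg[grid, on = c("context", "bin_index")]
  out[is.na(coverage), `:=`(coverage = 0, n_sites = 0L)]
  setorder(out, context, bin_index)
  out[]
}

#' Feature-anchored (metagene / meta-TE) methylation profile
#'
#' Average methylation as a function of position relative to a feature set:
#' fixed-width flanks (default 2 kb in 100-bp bins) plus a length-normalised
#' body (default 40 bins). Minus-strand features are reversed so bin 1 is
#' always the most distal upstream bin. Each bin value is the
#' coverage-weighted mean over all sites of all features falling in it.
#'
#' @param x A [methylome()].
#' @param features `GRanges` (or data.frame) of stranded features.
#' @param flank Flank width in bp (default 2000).
#' @param body_bins Number of length-normalised body bins (default 40).
#' @param flank_bin Flank bin width in bp (default 100).
#' @return A `meta_profile`: data.table (`context`, `bin_index`, `level`,
#'   `coverage`, `n_sites`) with attributes `anchor`, `flank_bins`,
#'   `body_bins`, `n_features`.
#' @export
metagene_profile <- function(x, features, flank = 2000L, body_bins = 40L,
                             flank_bin = 100L) {
  stopifnot(inherits(x, "methylome"))
  features <- .as_granges(features)
  if (!length(features)) stop("no features supplied")
  asg <- .metagene_assign(x$sites, features, flank, body_bins, flank_bin)
  n_bins <- 2L * as.integer(flank / flank_bin) + body_bins
  out <- .profile_from_assignment(asg, n_bins)
  setattr(out, "anchor", "feature")
  setattr(out, "flank_bins", as.integer(flank / flank_bin))
  setattr(out, "body_bins", as.integer(body_bins))
  setattr(out, "n_features", length(features))
  setattr(out, "class", c("meta_profile", class(out)))
  out[]
}

#' Region-centred methylation profile
#'
#' Profile around region midpoints (e.g. +/-2 kb from DMR centres): an odd
#' number of fixed-width bins, the central bin straddling the midpoint,
#' aggregated across regions by coverage-weighted mean.
#'
#' @param x A [methylome()].
#' @param regions `GRanges` or data.frame (`chrom`, `start`, `end`).
#' @param flank Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 100); yields `2*flank/bin + 1` bins.
#' @return A `meta_profile` data.table (`context`, `bin_index`, `level`,
#'   `coverage`, `n_sites`); bin `flank/bin + 1` is the centre.
#' @export
region_centered_profile <- function(x, regions, flank = 2000L, bin = 100L) {
  stopifnot(inherits(x, "methylome"))
  regions <- .as_granges(regions)
  if (!length(regions)) stop("no regions supplied")
  n_side <- as.integer(flank / bin)
  n_bins <- 2L * n_side + 1L
  reg <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(regions)),
    mid = (BiocGenerics::start(regions) + BiocGenerics::end(regions)) / 2)
  reg[, `:=`(wstart = as.integer(floor(mid - flank - bin / 2)),
             wend = as.integer(ceiling(mid + flank + bin / 2)))]
  s <- x$sites[, .(chrom, pos, context, n_meth, n_unmeth)]
  s[, `:=`(s1 = pos, s2 = pos)]
  setkey(reg, chrom, wstart, wend)
  ov <- foverlaps(s, reg, by.x = c("chrom", "s1", "s2"),
                  by.y = c("chrom", "wstart", "wend"), nomatch = NULL)
  if (nrow(ov)) {
    rel <- ov$pos - ov$mid                       # signed distance from centre
    bin_index <- n_side + 1L + as.integer(floor((rel + bin / 2) / bin))
    keep <- bin_index >= 1L & bin_index <= n_bins
    asg <- data.table(bin_index = bin_index[keep], context = ov$context[keep],
                      m = as.numeric(ov$n_meth[keep]),
                      t = as.numeric(ov$n_meth[keep] + ov$n_unmeth[keep]))
  } else {
    asg <- data.table(bin_index = integer(), context = character(),
                      m = numeric(), t = numeric())
  }
  out <- .profile_from_assignment(asg, n_bins)
  setattr(out, "anchor", "region-center")
  setattr(out, "n_features", length(regions))
  setattr(out, "class", c("meta_profile", class(out)))
  out[]
}

#' Per-trinucleotide site density and methylation level
#'
#' Summarises the 16 C-initial trinucleotides: how many sites carry each
#' subcontext, what fraction of all sites that is, and the coverage-weighted
#' methylation level.
#'
#' @param x A [methylome()].
#' @return data.table (`subcontext`, `context`, `n_sites`, `density`,
#'   `weighted_level`), one row per trinucleotide (zero rows filled in).
#' @export
subcontext_summary <- function(x) {
  stopifnot(inherits(x, "methylome"))
  if (!nrow(x$sites)) stop("methylome has no sites")
  per <- x$sites[, .(n_sites = .N,
                     weighted_level = sum(as.numeric(n_meth)) /
                       sum(as.numeric(n_meth) + as.numeric(n_unmeth))),
                 by = subcontext]
  grid <- data.table(subcontext = c_trinucleotides())
  out <- per[grid, on = "subcontext"]
  out[is.na(n_sites), n_sites := 0L]
  out[, density := n_sites / sum(n_sites)]
  out[, context := classify_subcontext(subcontext)]
  setcolorder(out, c("subcontext", "context", "n_sites", "density",
                     "weighted_level"))
  setorder(out, context, subcontext)
  out[]
}
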