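#' Configuration for the synthetic methylome study
#'
#' Defines a fully synthetic two-tissue (pulp, skin) by two-stage (immature,
#' ripe) WGBS study with duplicate libraries, emulating the statistical
#' structure of a ripening methylome experiment: context-specific baseline
#' levels (defaults: mCG 0.373, mCHG 0.160, mCHH 0.027), elevated CAA/CTA
#' CHH subcontexts, TE-body methylation enrichment, negative-binomial
#' coverage around 25x, beta-binomial replicate noise, a near-perfectly
#' converted chloroplast, and planted effects: ripening-induced CHH
#' hyper-DMRs with pulp/skin/both tissue scope, pre-existing inter-tissue
#' offsets on the skin-scope regions, promoter-bin hypermethylation of
#' designated responsive genes, and a matching differential-expression table.
#'
#' Background per-context levels are recentred so that the genome-wide
#' expected level equals the configured baseline after TE and inactive-gene
#' enrichment (enrichment redistributes methylation; it does not inflate the
#' global mean).
#'
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param n_chroms,chrom_length,chloroplast_length Genome layout (bp).
#' @param n_genes,n_tes Feature counts (split evenly across chromosomes).
#' @param gene_length,te_length Length ranges (bp).
#' @param coverage_mean,coverage_size Negative-binomial coverage model.
#' @param baselines Named per-context genome-wide target levels.
#' @param precision Beta-binomial precision (larger = less replicate noise).
#' @param te_boost,inactive_boost Named per-context additive enrichment in
#'   TE bodies and inactive-gene bodies/promoters.
#' @param n_dmr_pulp,n_dmr_skin,n_dmr_both Planted ripening-induced CHH
#'   hyper-DMR counts per tissue scope.
#' @param dmr_size Planted DMR length range (bp).
#' @param dmr_effect Added CHH level in planted DMRs at the ripe stage.
#' @param preexisting_offset Constant (both-stage) pulp CHH offset on the
#'   skin-scope regions — the synthetic analogue of pre-existing
#'   inter-tissue methylation differences.
#' @param n_responsive Named counts of planted methylation-responsive genes
#'   per tissue scope (`pulp`, `skin`, `both`).
#' @param responsive_bins,responsive_effect Number of 100-bp promoter bins
#'   (adjacent to the TSS) and added CHH level planted per responsive gene.
#' @param n_random_de Count of additional random DE genes.
#' @param frac_inactive Fraction of genes expressed below FPKM 1.
#' @param conversion_failure Chloroplast methylated-call rate (bisulfite
#'   conversion failure).
#' @param n_replicates Replicates per tissue x stage.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L,
                              chrom_length = 500000L,
                              chloroplast_length = 30000L,
                              n_genes = 200L, n_tes = 150L,
                              gene_length = c(1000L, 2500L),
                              te_length = c(400L, 1500L),
                              coverage_mean = 25, coverage_size = 10,
                              baselines = c(CG = 0.373, CHG = 0.160,
                                            CHH = 0.027),
                              precision = 50,
                              te_boost = c(CG = 0.25, CHG = 0.15, CHH = 0.02),
                              inactive_boost = c(CG = 0.15, CHG = 0.10,
                                                 CHH = 0.05),
                              n_dmr_pulp = 10L, n_dmr_skin = 10L,
                              n_dmr_both = 10L,
                              dmr_size = c(400L, 600L), dmr_effect = 0.15,
                              preexisting_offset = 0.10,
                              n_responsive = c(pulp = 4L, skin = 4L,
                                               both = 4L),
                              responsive_bins = 3L, responsive_effect = 0.15,
                              n_random_de = 30L, frac_inactive = 0.15,
                              conversion_failure = 0.003,
                              n_replicates = 2L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              chloroplast_length = as.integer(chloroplast_length),
              n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
              gene_length = as.integer(gene_length),
              te_length = as.integer(te_length),
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              baselines = baselines, precision = precision,
              te_boost = te_boost, inactive_boost = inactive_boost,
              n_dmr_pulp = as.integer(n_dmr_pulp),
              n_dmr_skin = as.integer(n_dmr_skin),
              n_dmr_both = as.integer(n_dmr_both),
              dmr_size = as.integer(dmr_size), dmr_effect = dmr_effect,
              preexisting_offset = preexisting_offset,
              n_responsive = n_responsive,
              responsive_bins = as.integer(responsive_bins),
              responsive_effect = responsive_effect,
              n_random_de = as.integer(n_random_de),
              frac_inactive = frac_inactive,
              conversion_failure = conversion_failure,
              n_replicates = as.integer(n_replicates))
  ctxs <- c("CG", "CHG", "CHH")
  if (!all(ctxs %in% names(cfg$baselines)) ||
      !all(ctxs %in% names(cfg$te_boost)) ||
      !all(ctxs %in% names(cfg$inactive_boost))) {
    stop("baselines, te_boost and inactive_boost must name CG, CHG, CHH")
  }
  if (any(cfg$baselines < 0 | cfg$baselines > 1) ||
      cfg$conversion_failure < 0 || cfg$conversion_failure > 1) {
    stop("levels must lie in [0, 1]")
  }
  worst <- max(cfg$baselines) + max(cfg$te_boost, cfg$inactive_boost) +
    cfg$dmr_effect + cfg$preexisting_offset
  if (worst > 1) {
    stop("planted effects can push levels above 1 (worst case ",
         round(worst, 3), "); reduce effects or baselines")
  }
  if (cfg$precision <= 0 || cfg$coverage_mean <= 0) {
    stop("precision and coverage_mean must be positive")
  }
  if (cfg$chrom_length < 10000L) stop("chrom_length must be >= 10000")
  structure(cfg, class = "simulation_config")
}

.complement <- function(b) chartr("ACGT", "TGCA", b)

## All strand-resolved cytosine sites of one sequence given as a character
## vector of bases: position, strand, trinucleotide on the cytosine strand.
## Sites without a complete trinucleotide (sequence edges) are skipped.
.cytosine_sites <- function(bases, chrom) {
  n <- length(bases)
  plus <- which(bases == "C")
  plus <- plus[plus <= n - 2L]
  comp <- .complement(bases)
  minus <- which(bases == "G")
  minus <- minus[minus >= 3L]
  dt <- rbind(
    data.table(pos = plus, strand = "+",
               subcontext = paste0(bases[plus], bases[plus + 1L],
                                   bases[plus + 2L])),
    data.table(pos = minus, strand = "-",
               subcontext = paste0(comp[minus], comp[minus - 1L],
                                   comp[minus - 2L])))
  dt[, chrom := chrom]
  dt[, context := classify_subcontext(subcontext)]
  setkeyv(dt, c("chrom", "pos", "strand"))
  dt[]
}

## Relative per-subcontext level multipliers; they average 1 within each
## context under uniform base composition, so the context mean stays at the
## configured background while CAA/CTA (and CAG/CTG) run hot.
.subcontext_multipliers <- function() {
  mult <- setNames(rep(1, 16L), c_trinucleotides())
  mult[c("CAA", "CTA")] <- 1.3
  chh <- setdiff(names(mult)[classify_subcontext(names(mult)) == "CHH"],
                 c("CAA", "CTA"))
  mult[chh] <- (9 - 2 * 1.3) / 7
  mult[c("CAG", "CTG")] <- 1.2
  mult["CCG"] <- 3 - 2 * 1.2
  mult
}

## Place n non-overlapping features of the given lengths on [1, len] with at
## least min_gap bp between them, spreading the slack uniformly at random.
.place_features <- function(n, lengths, len, min_gap = 200L) {
  if (!n) return(data.table(start = integer(), end = integer()))
  slack <- len - sum(lengths) - (n + 1L) * min_gap
  if (slack < 0) stop("features do not fit on sequence of length ", len)
  cuts <- sort(runif(n, 0, slack))
  extra <- floor(c(cuts[1L], diff(cuts)))
  starts <- min_gap + 1L + cumsum(extra) +
    c(0L, cumsum(lengths[-n] + min_gap))
  data.table(start = as.integer(starts),
             end = as.integer(starts + lengths - 1L))
}

#' Simulate a complete synthetic methylome study
#'
#' Generates genome, annotations, replicate methylomes for two tissues and
#' two stages, an expression table, and a truth manifest recording every
#' planted effect, per [simulation_config()]. Optionally writes everything
#' in the formats the IO module reads (FASTA, GFF3, cytosine-report TSV,
#' expression TSV, manifest JSON, accessibility BED).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; created if needed.
#' @return List of class `sim_study` with `genome` (DNAStringSet),
#'   `annotations` ([annotation_set()]), `samples` (named list of
#'   [methylome()]s), `expression` (data.table), `accessibility` (GRanges),
#'   `manifest` (list: `seed`, `dmrs`, `responsive_genes`, `preexisting`,
#'   `expression`, `config`), and `paths` when written.
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  seqs <- lapply(chrom_names, function(ch)
    sample(bases, config$chrom_length, replace = TRUE))
  names(seqs) <- chrom_names
  cp <- sample(bases, config$chloroplast_length, replace = TRUE)
  seqlengths <- c(setNames(rep(config$chrom_length, config$n_chroms),
                           chrom_names),
                  chloroplast = config$chloroplast_length)

  ## --- annotations -------------------------------------------------------
  split_counts <- function(total) {
    base_n <- total %/% config$n_chroms
    n <- rep(base_n, config$n_chroms)
    n[seq_len(total - base_n * config$n_chroms)] <-
      n[seq_len(total - base_n * config$n_chroms)] + 1L
    n
  }
  ng <- split_counts(config$n_genes)
  nt <- split_counts(config$n_tes)
  feats <- rbindlist(lapply(seq_along(chrom_names), function(i) {
    n_feat <- ng[i] + nt[i]
    type <- sample(rep(c("gene", "te"), c(ng[i], nt[i])))
    lens <- ifelse(type == "gene",
                   sample(config$gene_length[1L]:config$gene_length[2L],
                          n_feat, replace = TRUE),
                   sample(config$te_length[1L]:config$te_length[2L],
                          n_feat, replace = TRUE))
    pl <- .place_features(n_feat, lens, config$chrom_length)
    pl[, `:=`(chrom = chrom_names[i], type = type,
              strand = sample(c("+", "-"), n_feat, replace = TRUE))]
    pl
  }))
  feats[, id := ifelse(type == "gene",
                       sprintf("gene%04d", cumsum(type == "gene")),
                       sprintf("te%04d", cumsum(type == "te")))]
  genes <- feats[type == "gene"]
  tes <- feats[type == "te"]
  ann <- annotation_set(
    genes[, .(chrom, start, end, strand, id)],
    tes[, .(chrom, start, end, strand, id)],
    seqlengths, chloroplast_name = "chloroplast")

  ## --- planted regions ---------------------------------------------------
  n_dmrs <- c(pulp = config$n_dmr_pulp, skin = config$n_dmr_skin,
              both = config$n_dmr_both)
  total_dmrs <- sum(n_dmrs)
  ## gene promoters (2-kb strand-aware upstream) are kept free of planted
  ## DMRs so that promoter-level responsiveness is planted only through the
  ## designated responsive genes and the truth manifest stays complete
  promoters <- genes[, .(chrom,
                         start = pmax(1L, ifelse(strand == "+",
                                                 start - 2000L, end + 1L)),
                         end = pmin(config$chrom_length,
                                    ifelse(strand == "+", start - 1L,
                                           end + 2000L)))]
  dmrs <- data.table()
  if (total_dmrs) {
    sizes <- sample(config$dmr_size[1L]:config$dmr_size[2L], total_dmrs,
                    replace = TRUE)
    ## rejection-sample starts so planted regions stay >= 2 kb apart and
    ## clear of promoters
    placed <- data.table(chrom = character(), start = integer(),
                         end = integer())
    tries <- 0L
    while (nrow(placed) < total_dmrs && tries < 20000L) {
      tries <- tries + 1L
      i <- nrow(placed) + 1L
      ch <- sample(chrom_names, 1L)
      st <- sample.int(config$chrom_length - sizes[i] - 2000L, 1L) + 1000L
      cand_end <- st + sizes[i] - 1L
      clash <- placed[chrom == ch & start <= cand_end + 2000L &
                        end >= st - 2000L]
      prom_hit <- promoters[chrom == ch & start <= cand_end & end >= st]
      if (!nrow(clash) && !nrow(prom_hit)) {
        placed <- rbind(placed,
                        data.table(chrom = ch, start = st, end = cand_end))
      }
    }
    if (nrow(placed) < total_dmrs) stop("could not place planted DMRs")
    dmrs <- placed
    dmrs[, `:=`(scope = rep(names(n_dmrs), n_dmrs), context = "CHH",
                effect = config$dmr_effect, kind = "dmr",
                id = sprintf("dmr%03d", .I))]
  }

  ## --- responsive genes --------------------------------------------------
  n_resp <- config$n_responsive
  resp <- data.table()
  if (sum(n_resp)) {
    ## promoter interval upstream of the TSS, clear of sequence edges
    g <- copy(genes)
    g[, `:=`(prom_start = ifelse(strand == "+", start - 2000L, end + 1L),
             prom_end = ifelse(strand == "+", start - 1L, end + 2000L))]
    ok <- g[prom_start >= 1L & prom_end <= config$chrom_length]
    ## the planted window (TSS-adjacent bins) must not fall inside another
    ## gene's promoter, or that neighbour would become an unrecorded
    ## responsive gene
    span0 <- config$responsive_bins * 100L
    ok[, `:=`(w_start = ifelse(strand == "+", start - span0, end + 1L),
              w_end = ifelse(strand == "+", start - 1L, end + span0))]
    clear <- vapply(seq_len(nrow(ok)), function(i) {
      !any(promoters$chrom == ok$chrom[i] & genes$id != ok$id[i] &
             promoters$start <= ok$w_end[i] & promoters$end >= ok$w_start[i])
    }, logical(1L))
    ok <- ok[clear]
    if (nrow(ok) < sum(n_resp)) {
      stop("not enough genes with isolated promoters for responsive plants")
    }
    pick <- sample(nrow(ok), sum(n_resp))
    resp <- ok[pick]
    resp[, scope := rep(names(n_resp), n_resp)]
    ## planted bins sit adjacent to the TSS: bins 1..responsive_bins
    span <- config$responsive_bins * 100L
    resp[, `:=`(eff_start = ifelse(strand == "+", start - span, end + 1L),
                eff_end = ifelse(strand == "+", start - 1L, end + span))]
  }
  effects <- rbind(
    if (nrow(dmrs)) dmrs[, .(chrom, start, end, context, scope, effect,
                             stage_scope = "ripe", kind, id)],
    if (nrow(resp)) resp[, .(chrom, start = eff_start, end = eff_end,
                             context = "CHH", scope,
                             effect = config$responsive_effect,
                             stage_scope = "ripe", kind = "promoter",
                             id = paste0("resp_", id))],
    ## pre-existing pulp offset on the skin-scope planted DMRs (both stages)
    if (nrow(dmrs) && config$preexisting_offset > 0)
      dmrs[scope == "skin",
           .(chrom, start, end, context, scope = "pulp",
             effect = config$preexisting_offset, stage_scope = "both",
             kind = "preexisting", id = paste0("pre_", id))])
  if (is.null(effects)) {
    effects <- data.table(chrom = character(), start = integer(),
                          end = integer(), context = character(),
                          scope = character(), effect = numeric(),
                          stage_scope = character(), kind = character(),
                          id = character())
  }

  ## --- expression --------------------------------------------------------
  inactive <- runif(nrow(genes)) < config$frac_inactive
  if (nrow(resp)) inactive[match(resp$id, genes$id)] <- FALSE
  fpkm_base <- ifelse(inactive, runif(nrow(genes), 0, 0.8),
                      pmax(1.2, exp(rnorm(nrow(genes), log(20), 1))))
  expr <- CJ(gene_id = genes$id, tissue = c("pulp", "skin"), sorted = FALSE)
  expr <- merge(expr,
                data.table(gene_id = genes$id, base = fpkm_base,
                           inactive = inactive),
                by = "gene_id", sort = FALSE)
  expr[, `:=`(fpkm_immature = round(base, 3),
              fpkm_ripe = round(base * 2^rnorm(.N, 0, 0.1), 3),
              de_direction = "none")]
  ## planted DE: responsive genes are downregulated in their scope tissue
  if (nrow(resp)) {
    for (i in seq_len(nrow(resp))) {
      tis <- if (resp$scope[i] == "both") c("pulp", "skin") else resp$scope[i]
      expr[gene_id == resp$id[i] & tissue %in% tis,
           `:=`(fpkm_ripe = round(fpkm_immature / 4, 3),
                de_direction = "down")]
    }
  }
  if (config$n_random_de) {
    pool <- setdiff(genes$id[!inactive],
                    if (nrow(resp)) resp$id else character())
    de_pick <- sample(pool, min(config$n_random_de, length(pool)))
    de_dir <- sample(c("up", "down"), length(de_pick), replace = TRUE)
    de_tis <- sample(c("pulp", "skin", "both"), length(de_pick),
                     replace = TRUE)
    for (i in seq_along(de_pick)) {
      tis <- if (de_tis[i] == "both") c("pulp", "skin") else de_tis[i]
      fold <- if (de_dir[i] == "up") 4 else 0.25
      expr[gene_id == de_pick[i] & tissue %in% tis,
           `:=`(fpkm_ripe = round(pmax(fpkm_immature * fold, 0.01), 3),
                de_direction = de_dir[i])]
    }
  }
  expr[, c("base") := NULL]

  ## --- true methylation levels ------------------------------------------
  sites <- rbindlist(lapply(chrom_names, function(ch)
    .cytosine_sites(seqs[[ch]], ch)))
  mult <- .subcontext_multipliers()
  te_mask <- .sites_in_regions(sites, tes[, .(chrom, start, end)])
  inact_regions <- rbind(
    genes[inactive, .(chrom, start, end)],
    genes[inactive, .(chrom,
                      start = pmax(1L, ifelse(strand == "+", start - 2000L,
                                              end + 1L)),
                      end = pmin(config$chrom_length,
                                 ifelse(strand == "+", start - 1L,
                                        end + 2000L)))])
  inact_mask <- .sites_in_regions(sites, inact_regions[start <= end]) &
    !te_mask
  base_levels <- numeric(nrow(sites))
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- sites$context == ctx
    f_te <- mean(te_mask[sel])
    f_in <- mean(inact_mask[sel])
    bg <- config$baselines[[ctx]] - config$te_boost[[ctx]] * f_te -
      config$inactive_boost[[ctx]] * f_in
    bg <- max(bg, 0.001)
    base_levels[sel] <- bg * mult[sites$subcontext[sel]] +
      config$te_boost[[ctx]] * te_mask[sel] +
      config$inactive_boost[[ctx]] * inact_mask[sel]
  }
  sites[, base_level := pmin(pmax(base_levels, 0), 1)]

  cp_sites <- .cytosine_sites(cp, "chloroplast")
  cp_sites[, base_level := config$conversion_failure]

  ## --- draw samples ------------------------------------------------------
  ## Site-level biological heterogeneity: each site's latent level is a
  ## beta draw (at the configured precision) around its structural base
  ## level, made once per tissue and shared by that tissue's stages and
  ## replicates. Planted effects shift the latent additively, so unplanted
  ## sites are exactly null across stages; replicates differ only through
  ## negative-binomial coverage and binomial sampling. Observed counts are
  ## therefore marginally beta-binomial across sites.
  latent <- lapply(c(pulp = "pulp", skin = "skin"), function(tis)
    .rbeta_noise(sites$base_level, config$precision))
  samples <- list()
  for (tis in c("pulp", "skin")) {
    for (stg in c("immature", "ripe")) {
      lvl <- latent[[tis]]
      if (nrow(effects)) {
        eff <- effects[scope %in% c(tis, "both") &
                         (stage_scope == "both" | stage_scope == stg)]
        if (nrow(eff)) {
          hit <- .sites_effect_sum(sites, eff)
          lvl <- pmin(lvl + hit, 1)
        }
      }
      for (rep_i in seq_len(config$n_replicates)) {
        sid <- sprintf("%s_%s_rep%d", tis, stg, rep_i)
        cov_n <- rnbinom(nrow(sites), mu = config$coverage_mean,
                         size = config$coverage_size)
        n_meth <- rbinom(nrow(sites), cov_n, lvl)
        cov_cp <- rnbinom(nrow(cp_sites), mu = config$coverage_mean,
                          size = config$coverage_size)
        m_cp <- rbinom(nrow(cp_sites), cov_cp, config$conversion_failure)
        tab <- rbind(
          sites[, .(chrom, pos, strand, subcontext, context)][,
            `:=`(n_meth = n_meth, n_unmeth = cov_n - n_meth)],
          cp_sites[, .(chrom, pos, strand, subcontext, context)][,
            `:=`(n_meth = m_cp, n_unmeth = cov_cp - m_cp)])
        samples[[sid]] <- methylome(
          tab[n_meth + n_unmeth > 0L], sample_id = sid,
          cultivar = "synthetic", tissue = tis, stage = stg,
          replicate = rep_i)
      }
    }
  }

  accessibility <- GenomicRanges::GRanges(
    genes$chrom[!inactive],
    IRanges::IRanges(
      pmax(1L, ifelse(genes$strand[!inactive] == "+",
                      genes$start[!inactive] - 500L,
                      genes$end[!inactive] + 1L)),
      pmin(config$chrom_length,
           ifelse(genes$strand[!inactive] == "+",
                  genes$start[!inactive] - 1L,
                  genes$end[!inactive] + 500L))))

  manifest <- list(
    seed = config$seed,
    dmrs = if (nrow(dmrs)) dmrs[, .(id, chrom, start, end, scope, context,
                                    effect)] else data.table(),
    promoter_effects = if (nrow(resp))
      resp[, .(gene_id = id, chrom, start = eff_start, end = eff_end, scope,
               effect = config$responsive_effect)] else data.table(),
    responsive_genes = if (nrow(resp))
      resp[, .(gene_id = id, scope)] else data.table(),
    preexisting = if (nrow(effects))
      effects[kind == "preexisting",
              .(id, chrom, start, end, scope, effect)] else data.table(),
    expression = expr,
    config = unclass(config))

  genome <- Biostrings::DNAStringSet(
    c(vapply(seqs, paste, character(1L), collapse = ""),
      chloroplast = paste(cp, collapse = "")))

  out <- structure(list(genome = genome, annotations = ann,
                        samples = samples, expression = expr,
                        accessibility = accessibility, manifest = manifest),
                   class = "sim_study")
  if (!is.null(out_dir)) out$paths <- write_study(out, out_dir)
  out
}

## logical: is each site inside any region of the set
.sites_in_regions <- function(sites, regions) {
  out <- logical(nrow(sites))
  if (!nrow(regions)) return(out)
  s <- sites[, .(chrom, s1 = pos, s2 = pos, idx = .I)]
  reg <- as.data.table(regions)[, .(chrom, start, end)]
  setkey(reg, chrom, start, end)
  ov <- foverlaps(s, reg, by.x = c("chrom", "s1", "s2"),
                  by.y = c("chrom", "start", "end"), nomatch = NULL)
  out[unique(ov$idx)] <- TRUE
  out
}

## numeric: summed effect over all matching effect intervals per site
.sites_effect_sum <- function(sites, eff) {
  out <- numeric(nrow(sites))
  s <- sites[, .(chrom, context, s1 = pos, s2 = pos, idx = .I)]
  reg <- eff[, .(chrom, start, end, context, effect)]
  setkey(reg, chrom, start, end)
  ov <- foverlaps(s, reg, by.x = c("chrom", "s1", "s2"),
                  by.y = c("chrom", "start", "end"), nomatch = NULL)
  ov <- ov[context == i.context]
  if (nrow(ov)) {
    add <- ov[, .(e = sum(effect)), by = idx]
    out[add$idx] <- add$e
  }
  out
}

## beta noise around a level vector; degenerate levels stay degenerate
.rbeta_noise <- function(lvl, precision) {
  p <- numeric(length(lvl))
  inner <- lvl > 0 & lvl < 1
  p[inner] <- rbeta(sum(inner), lvl[inner] * precision,
                    (1 - lvl[inner]) * precision)
  p[lvl >= 1] <- 1
  p
}

#' Write a simulated study to disk
#'
#' Emits exactly the formats the IO module reads: `genome.fa`,
#' `annotations.gff3`, one `<sample_id>.cx.tsv` per sample,
#' `expression.tsv`, `accessibility.bed` and `manifest.json`.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(out_dir, "genome.fa"),
                gff = file.path(out_dir, "annotations.gff3"),
                expression = file.path(out_dir, "expression.tsv"),
                accessibility = file.path(out_dir, "accessibility.bed"),
                manifest = file.path(out_dir, "manifest.json"))
  Biostrings::writeXStringSet(study$genome, paths$genome)
  ann <- study$annotations
  gff <- c(ann$genes, ann$tes)
  gff$type <- rep(c("gene", "transposable_element"),
                  c(length(ann$genes), length(ann$tes)))
  gff$ID <- gff$id
  rtracklayer::export(gff, paths$gff, format = "gff3")
  fwrite(study$expression, paths$expression, sep = "\t")
  rtracklayer::export(study$accessibility, paths$accessibility,
                      format = "bed")
  man <- study$manifest
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  for (sid in names(study$samples)) {
    paths[[paste0("sample_", sid)]] <-
      file.path(out_dir, paste0(sid, ".cx.tsv"))
    write_cytosine_report(study$samples[[sid]],
                          paths[[paste0("sample_", sid)]])
  }
  invisible(paths)
}

## fraction of each truth interval covered by the best single call decides a
## match (>= min_frac of the planted interval)
.match_planted <- function(truth, calls, min_frac = 0.5) {
  if (!nrow(truth)) return(integer())
  matched <- rep(NA_integer_, nrow(truth))
  if (!nrow(calls)) return(matched)
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  cg <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  ov <- GenomicRanges::findOverlaps(tg, cg)
  if (!length(ov)) return(matched)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- pmin(truth$end[q], calls$end[s]) -
    pmax(truth$start[q], calls$start[s]) + 1L
  frac <- inter / (truth$end[q] - truth$start[q] + 1L)
  keep <- frac >= min_frac
  if (any(keep)) {
    dt <- data.table(q = q[keep], s = s[keep], frac = frac[keep])
    best <- dt[order(-frac), .SD[1L], by = q]
    matched[best$q] <- best$s
  }
  matched
}

## indices of calls that cover >= min_frac of at least one truth interval
.calls_matching_truth <- function(truth, calls, min_frac = 0.5) {
  if (!nrow(truth) || !nrow(calls)) return(integer())
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  cg <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  ov <- GenomicRanges::findOverlaps(tg, cg)
  if (!length(ov)) return(integer())
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- pmin(truth$end[q], calls$end[s]) -
    pmax(truth$start[q], calls$start[s]) + 1L
  frac <- inter / (truth$end[q] - truth$start[q] + 1L)
  sort(unique(s[frac >= min_frac]))
}

#' Score recovery of planted effects from pipeline calls
#'
#' A called DMR matches a planted interval when it covers at least half of
#' it. Per tissue: recall over the planted ripening-induced DMRs in scope,
#' precision over all calls (a call is a true positive when it matches any
#' planted hyper interval in scope, including planted promoter effects).
#' With group assignments, accuracy of the tissue-scope label over matched
#' planted DMRs; with responsive-gene calls, set precision/recall of the
#' responsive verdicts.
#'
#' @param manifest The `manifest` of a [simulate_study()] result.
#' @param pulp_dmrs,skin_dmrs Called `dmr_regions` for the two ripening
#'   comparisons (CHH hyper regions are used).
#' @param assignments Optional result of [classify_dmr_groups()].
#' @param pulp_responsive,skin_responsive Optional `responsive_calls`.
#' @return List with `dmr` (per-tissue recall/precision; precision `NA`
#'   when there are no calls), `group_accuracy` (or `NA`), and `responsive`
#'   (per-tissue precision/recall, when supplied).
#' @export
score_recovery <- function(manifest, pulp_dmrs = NULL, skin_dmrs = NULL,
                           assignments = NULL, pulp_responsive = NULL,
                           skin_responsive = NULL) {
  planted <- as.data.table(manifest$dmrs)
  prom <- as.data.table(manifest$promoter_effects)
  calls <- list(pulp = pulp_dmrs, skin = skin_dmrs)
  dmr_scores <- rbindlist(lapply(c("pulp", "skin"), function(tis) {
    cl <- calls[[tis]]
    if (is.null(cl)) return(NULL)
    cl <- as.data.table(cl)
    if (nrow(cl)) cl <- cl[context == "CHH" & direction == "hyper"]
    tr <- planted[scope %in% c(tis, "both")]
    all_truth <- rbind(tr[, .(chrom, start, end)],
                       if (nrow(prom))
                         prom[scope %in% c(tis, "both"),
                              .(chrom, start, end)])
    m_recall <- .match_planted(tr, cl)
    recall <- if (nrow(tr)) mean(!is.na(m_recall)) else NA_real_
    precision <- if (nrow(cl)) {
      ## a call is a true positive when it covers >= 50% of any planted
      ## hyper interval in scope (planted DMRs or promoter plants)
      length(.calls_matching_truth(all_truth, cl)) / nrow(cl)
    } else NA_real_
    data.table(tissue = tis, n_planted = nrow(tr), n_called = nrow(cl),
               recall = recall, precision = precision)
  }))
  group_accuracy <- NA_real_
  if (!is.null(assignments) && nrow(planted)) {
    expected <- c(pulp = "pulp_specific", skin = "skin_specific",
                  both = "common")
    asn <- rbind(
      assignments$assignments[group != "common",
                              .(chrom, start, end, group)],
      assignments$common_regions[, .(chrom, start, end, group = "common")])
    m <- .match_planted(planted, asn)
    ok <- !is.na(m)
    if (any(ok)) {
      group_accuracy <- mean(asn$group[m[ok]] ==
                               expected[planted$scope[ok]])
    }
  }
  responsive <- NULL
  resp_truth <- as.data.table(manifest$responsive_genes)
  resp_calls <- list(pulp = pulp_responsive, skin = skin_responsive)
  if (!is.null(pulp_responsive) || !is.null(skin_responsive)) {
    responsive <- rbindlist(lapply(c("pulp", "skin"), function(tis) {
      rc <- resp_calls[[tis]]
      if (is.null(rc)) return(NULL)
      called <- as.data.table(rc)[responsive_hyper == TRUE, gene_id]
      truth_genes <- if (nrow(resp_truth))
        resp_truth[scope %in% c(tis, "both"), gene_id] else character()
      tp <- length(intersect(called, truth_genes))
      data.table(tissue = tis,
                 precision = if (length(called)) tp / length(called)
                 else NA_real_,
                 recall = if (length(truth_genes)) tp / length(truth_genes)
                 else NA_real_)
    }))
  }
  list(dmr = dmr_scores, group_accuracy = group_accuracy,
       responsive = responsive)
}
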