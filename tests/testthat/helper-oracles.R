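# Independent oracles and fixture builders. These deliberately use different
# computational routes from the package implementation.

library(data.table)

# Binomial LRT via dbinom() at the MLEs (the choose() terms cancel in the
# ratio, so this equals the raw log-likelihood difference).
oracle_lrt <- function(m_a, t_a, m_b, t_b) {
  ll <- function(m, t, p) dbinom(m, t, p, log = TRUE)
  p_a <- m_a / t_a
  p_b <- m_b / t_b
  p_0 <- (m_a + m_b) / (t_a + t_b)
  stat <- 2 * (ll(m_a, t_a, p_a) + ll(m_b, t_b, p_b) -
                 ll(m_a, t_a, p_0) - ll(m_b, t_b, p_0))
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       difference = p_b - p_a)
}

# Brute-force DMR caller: enumerate every step-aligned window along [1, len],
# mark the bases of windows holding >= min_dmcs DMCs, merge runs separated by
# <= merge_gap, count member DMCs, filter, trim to outermost members.
oracle_dmrs <- function(pos, len, window = 200L, step = 50L,
                        merge_gap = 100L, min_dmcs = 10L) {
  covered <- logical(len)
  for (s in seq.int(1L, len, by = step)) {
    e <- s + window - 1L
    if (sum(pos >= s & pos <= e) >= min_dmcs) {
      covered[s:min(e, len)] <- TRUE
    }
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  regions <- data.table(start = starts[runs$values], end = ends[runs$values])
  if (!nrow(regions)) {
    return(data.table(start = integer(), end = integer(),
                      n_dmcs = integer()))
  }
  # merge regions separated by <= merge_gap
  merged <- regions[1L]
  if (nrow(regions) > 1L) {
    for (i in 2:nrow(regions)) {
      gap <- regions$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- regions$end[i]
      } else {
        merged <- rbind(merged, regions[i])
      }
    }
  }
  out <- merged[, {
    member <- pos[pos >= start & pos <= end]
    list(n_dmcs = length(member),
         trim_start = if (length(member)) min(member) else NA_integer_,
         trim_end = if (length(member)) max(member) else NA_integer_)
  }, by = .(start, end)]
  out <- out[n_dmcs >= min_dmcs,
             .(start = trim_start, end = trim_end, n_dmcs)]
  setorder(out, start)
  out[]
}

# Exact two-sided Wilcoxon p by full enumeration of all rank assignments.
oracle_wilcoxon_perm <- function(a, b) {
  n_a <- length(a)
  vals <- c(a, b)
  ranks <- rank(vals)
  obs <- sum(ranks[seq_len(n_a)])
  combs <- utils::combn(length(vals), n_a)
  sums <- apply(combs, 2L, function(idx) sum(ranks[idx]))
  mu <- n_a * (length(vals) + 1) / 2
  p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
  p
}

# Minimal DMC-call table at the given positions (context/direction uniform).
make_dmcs <- function(pos, direction = "hyper", context = "CHH",
                      chrom = "chr1") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = "+",
             context = context, level_a = 0.01, level_b = 0.2,
             difference = ifelse(direction == "hyper", 0.19, -0.19),
             statistic = 30, p_value = 1e-7, t_a = 100, t_b = 100,
             direction = direction)
}

# A methylome with every site at the same exact level (counts lvl_num out of
# lvl_den), all three contexts represented, deterministic layout.
constant_methylome <- function(len = 4000L, lvl_num = 1L, lvl_den = 2L,
                               chrom = "chrA", every = 7L, ...) {
  pos <- seq.int(3L, len - 3L, by = every)
  subs <- rep(c("CGA", "CAG", "CAA", "CTA", "CCG", "CCC"),
              length.out = length(pos))
  methylome(data.table(chrom = chrom, pos = pos,
                       strand = rep(c("+", "-"), length.out = length(pos)),
                       n_meth = lvl_num, n_unmeth = lvl_den - lvl_num,
                       subcontext = subs), ...)
}

# A methylome whose CHH level differs between supplied regions and background.
patterned_methylome <- function(len, regions, level_in, level_out,
                                chrom = "chrA", coverage = 100L,
                                every = 5L, ...) {
  pos <- seq.int(3L, len - 3L, by = every)
  lvl <- rep(level_out, length(pos))
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      sel <- pos >= regions$start[i] & pos <= regions$end[i]
      lvl[sel] <- level_in
    }
  }
  n_meth <- as.integer(round(lvl * coverage))
  methylome(data.table(chrom = chrom, pos = pos, strand = "+",
                       n_meth = n_meth, n_unmeth = coverage - n_meth,
                       subcontext = "CAA"), ...)
}

# Small simulated study shared by several tests (cached per session).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(simulation_config(
        seed = 42L, n_chroms = 1L, chrom_length = 120000L,
        chloroplast_length = 20000L, n_genes = 24L, n_tes = 18L,
        n_dmr_pulp = 2L, n_dmr_skin = 2L, n_dmr_both = 2L,
        n_responsive = c(pulp = 1L, skin = 1L, both = 1L),
        n_random_de = 5L))
    }
    cache
  }
})
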