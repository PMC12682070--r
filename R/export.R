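#' Export DMRs or DMCs as BED
#'
#' BED6+ with 0-based half-open coordinates as the format requires: name is
#' `context:direction`, score is the region's mean difference scaled to
#' 0-1000 (DMRs) or `-log10(p)` capped at 1000 (DMCs).
#'
#' @param x A `dmr_regions` or `dmc_calls` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path) {
  dt <- as.data.table(x)
  if (!nrow(dt)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if ("n_dmcs" %in% names(dt)) {
    bed <- dt[, .(chrom, start = start - 1L, end,
                  name = paste0(context, ":", direction),
                  score = pmin(1000L,
                               as.integer(round(abs(mean_difference) * 1000))),
                  strand = ".")]
  } else {
    bed <- dt[, .(chrom, start = pos - 1L, end = pos,
                  name = paste0(context, ":", direction),
                  score = pmin(1000L,
                               as.integer(round(-log10(pmax(p_value,
                                                            1e-100))))),
                  strand = strand)]
  }
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export a bin track as bedGraph
#'
#' One bedGraph per call, for a single context's level column; bins without
#' covered sites are skipped.
#'
#' @param track A `bin_track` from [bin_genome()].
#' @param path Output path.
#' @param context Context level column to export.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path, context = "CHH") {
  lvl <- paste0("level_", context)
  dt <- as.data.table(track)[!is.na(get(lvl)),
                             .(chrom, start = start - 1L, end,
                               value = get(lvl))]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
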