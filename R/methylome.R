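#' Construct a sample methylome
#'
#' A `methylome` bundles the per-cytosine counts of one WGBS sample with its
#' design metadata (cultivar, tissue, developmental stage, replicate). Sites
#' are strand-resolved: CG cytosines on opposite strands are kept as
#' independent sites, matching per-cytosine extractor output; they are never
#' merged into dyads.
#'
#' @param sites A data.frame/data.table with columns `chrom`, `pos` (1-based
#'   position of the cytosine), `strand` (`"+"`/`"-"`), `n_meth`, `n_unmeth`,
#'   `subcontext` (trinucleotide on the cytosine's strand) and optionally
#'   `context`; if `context` is present it is validated against the
#'   subcontext, otherwise it is derived.
#' @param sample_id,cultivar,tissue,stage,replicate Sample metadata. `tissue`
#'   is typically one of `whole`, `skin`, `pulp`; `stage` one of `immature`,
#'   `veraison`, `ripe`.
#' @return An object of class `methylome`: a list with `sites` (a keyed
#'   data.table sorted by chrom, pos, strand) and the metadata fields.
#' @export
methylome <- function(sites, sample_id = "sample", cultivar = NA_character_,
                      tissue = NA_character_, stage = NA_character_,
                      replicate = 1L) {
  dt <- as.data.table(sites)
  required <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "subcontext")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(dt)) {
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0)) {
      stop("counts must be non-negative")
    }
    derived <- classify_subcontext(dt$subcontext)
    if ("context" %in% names(dt)) {
      bad <- which(dt$context != derived)
      if (length(bad)) {
        stop("context/subcontext mismatch at row(s) ",
             paste(head(bad, 5L), collapse = ", "),
             " (e.g. ", dt$subcontext[bad[1L]], " labelled ",
             dt$context[bad[1L]], ")")
      }
    }
    dt[, context := derived]
    dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
                 strand = as.character(strand),
                 n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
                 context = context, subcontext = as.character(subcontext))]
    setkeyv(dt, c("chrom", "pos", "strand"))
    dup <- duplicated(dt, by = c("chrom", "pos", "strand"))
    if (any(dup)) {
      d1 <- dt[which(dup)[1L]]
      stop("duplicate site at ", d1$chrom, ":", d1$pos, " strand ", d1$strand)
    }
  } else {
    dt <- data.table(chrom = character(), pos = integer(),
                     strand = character(), n_meth = integer(),
                     n_unmeth = integer(), context = character(),
                     subcontext = character())
    setkeyv(dt, c("chrom", "pos", "strand"))
  }
  structure(list(sites = dt, sample_id = sample_id, cultivar = cultivar,
                 tissue = tissue, stage = stage,
                 replicate = as.integer(replicate)),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat("<methylome> ", x$sample_id,
      sprintf(" [%s / %s / %s / rep %s]\n",
              x$cultivar, x$tissue, x$stage, x$replicate))
  cat("  sites: ", nrow(x$sites), " on ",
      length(unique(x$sites$chrom)), " sequence(s)\n", sep = "")
  if (nrow(x$sites)) {
    lv <- global_levels(x)
    cat("  weighted levels:",
        paste(sprintf("%s=%.3f", lv$context, lv$weighted_level),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Read a per-cytosine count report
#'
#' Reads a tab-separated cytosine report in the Bismark CX-report dialect:
#' columns `chrom`, `pos` (1-based), `strand`, `count_methylated`,
#' `count_unmethylated`, `context`, `trinucleotide`, no header. gzip input is
#' handled transparently. The context column is recomputed from the
#' trinucleotide and mismatches rejected. Sites below the depth cutoff are
#' dropped; the remainder is sorted and checked for duplicates.
#'
#' @param path Path to the report (optionally gzipped).
#' @param min_depth Minimum total read depth (`n_meth + n_unmeth`) for a site
#'   to be retained. Default 4, the usual validity filter for WGBS.
#' @param ... Metadata passed on to [methylome()] (`sample_id`, `tissue`, ...).
#' @return A [methylome()].
#' @export
read_cytosine_report <- function(path, min_depth = 4L, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context",
            "subcontext")
  if (file.size(path) == 0L) {
    return(methylome(data.table(chrom = character(), pos = integer(),
                                strand = character(), n_meth = integer(),
                                n_unmeth = integer(),
                                subcontext = character()), ...))
  }
  dt <- tryCatch(
    fread(path, sep = "\t", header = FALSE, col.names = cols,
          colClasses = list(character = c(1L, 3L, 6L, 7L),
                            integer = c(2L, 4L, 5L))),
    error = function(e) stop("malformed cytosine report '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt)) {
    bad <- which(is.na(dt$pos) | is.na(dt$n_meth) | is.na(dt$n_unmeth))
    if (length(bad)) {
      stop("malformed cytosine report '", path, "' at line ", bad[1L],
           ": non-numeric count or position")
    }
    dt <- dt[n_meth + n_unmeth >= min_depth]
  }
  methylome(dt, ...)
}

#' Write a methylome as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: tab-separated, no header, columns
#' chrom, pos, strand, methylated count, unmethylated count, context,
#' trinucleotide.
#'
#' @param x A [methylome()].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  fwrite(x$sites[, .(chrom, pos, strand, n_meth, n_unmeth, context,
                     subcontext)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Depth-filter a methylome
#'
#' @param x A [methylome()].
#' @param min_depth Minimum `n_meth + n_unmeth`.
#' @return A filtered [methylome()]; sorted order is preserved.
#' @export
filter_depth <- function(x, min_depth) {
  stopifnot(inherits(x, "methylome"))
  x$sites <- x$sites[n_meth + n_unmeth >= min_depth]
  x
}

#' Bisulfite conversion QC from chloroplast methylation
#'
#' The chloroplast genome is essentially unmethylated, so any methylated
#' calls there measure incomplete bisulfite conversion. The conversion rate
#' is `1 - sum(n_meth) / sum(n_meth + n_unmeth)` over chloroplast sites
#' (coverage-weighted). Failure against the threshold is reported, not
#' enforced: downstream analysis proceeds with the QC flag attached.
#'
#' @param x A [methylome()].
#' @param chloroplast_name Sequence name of the chloroplast.
#' @param threshold Minimum acceptable conversion rate (default 0.99).
#' @return A list with `rate`, `pass`, `threshold`, `n_sites`,
#'   `total_coverage`. Errors if the sample has no chloroplast sites (the QC
#'   is unavailable, never silently perfect).
#' @export
conversion_rate <- function(x, chloroplast_name, threshold = 0.99) {
  stopifnot(inherits(x, "methylome"))
  cp <- x$sites[chrom == chloroplast_name]
  if (!nrow(cp)) {
    stop("QC unavailable: no sites on chloroplast sequence '",
         chloroplast_name, "' in sample ", x$sample_id)
  }
  tot <- sum(as.numeric(cp$n_meth) + as.numeric(cp$n_unmeth))
  if (tot == 0) {
    stop("QC unavailable: chloroplast sites have zero total coverage")
  }
  rate <- 1 - sum(as.numeric(cp$n_meth)) / tot
  pass <- rate >= threshold
  if (!pass) {
    warning(sprintf("conversion rate %.4f below threshold %.4f in sample %s",
                    rate, threshold, x$sample_id))
  }
  list(rate = rate, pass = pass, threshold = threshold,
       n_sites = nrow(cp), total_coverage = tot)
}
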