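#' Construct an annotation set
#'
#' Holds gene and transposable-element (TE) intervals plus the sequence
#' lengths they live on and the name of the chloroplast sequence used for
#' conversion QC. Intervals are `GRanges` (1-based closed, the Bioconductor
#' convention); every interval is validated against the sequence lengths.
#'
#' @param genes,tes `GRanges` (or coercible data.frames with `chrom`,
#'   `start`, `end`, `strand`, `id`) of gene and TE intervals.
#' @param seqlengths Named integer vector of sequence lengths.
#' @param chloroplast_name Sequence name used for conversion QC (may be
#'   `NA` when no chloroplast is present).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, tes, seqlengths,
                           chloroplast_name = NA_character_) {
  genes <- .as_granges(genes)
  tes <- .as_granges(tes)
  seqlengths <- .as_seqlengths(seqlengths)
  for (what in c("genes", "tes")) {
    gr <- if (what == "genes") genes else tes
    if (!length(gr)) next
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chr), names(seqlengths))
    if (length(unknown)) {
      stop(what, " on unknown sequence(s): ", paste(unknown, collapse = ", "))
    }
    over <- BiocGenerics::end(gr) > seqlengths[chr] | BiocGenerics::start(gr) < 1L
    if (any(over)) {
      i <- which(over)[1L]
      stop(what, " interval beyond sequence bounds: ",
           chr[i], ":", BiocGenerics::start(gr)[i], "-",
           BiocGenerics::end(gr)[i],
           " (length ", seqlengths[chr[i]], ")")
    }
  }
  structure(list(genes = genes, tes = tes, seqlengths = seqlengths,
                 chloroplast_name = chloroplast_name),
            class = "annotation_set")
}

.as_granges <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (methods::is(x, "GRanges")) return(x)
  dt <- as.data.table(x)
  if (!nrow(dt)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start, end = dt$end),
    strand = if ("strand" %in% names(dt)) dt$strand else "*")
  gr$id <- if ("id" %in% names(dt)) dt$id else paste0("feat", seq_len(nrow(dt)))
  gr
}

.as_seqlengths <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fa <- Biostrings::readDNAStringSet(x)
    out <- Biostrings::width(fa)
    names(out) <- sub("\\s.*$", "", names(fa))
    return(out)
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  out <- as.integer(x)
  names(out) <- names(x)
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$genes), " genes, ", length(x$tes),
      " TEs on ", length(x$seqlengths), " sequence(s)",
      if (!is.na(x$chloroplast_name))
        paste0(" (chloroplast: ", x$chloroplast_name, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read gene/TE annotations against a genome
#'
#' Genes are taken from GFF3 features of type `gene`; TEs from features of
#' type `transposable_element`/`TE`/`repeat_region` in the same GFF3 or from
#' a separate GFF3/BED file. All intervals are bounds-checked against the
#' genome FASTA.
#'
#' @param gff_path GFF3 file with gene (and optionally TE) features.
#' @param genome FASTA path, or a named vector of sequence lengths.
#' @param te_path Optional separate GFF3 or BED file of TE intervals.
#' @param chloroplast_name Sequence name used for conversion QC; defaults to
#'   a sequence literally named `"chloroplast"` when present.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(gff_path, genome, te_path = NULL,
                             chloroplast_name = NULL) {
  seqlengths <- .as_seqlengths(genome)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  types <- as.character(gff$type)
  genes <- gff[types == "gene"]
  if (length(genes)) {
    genes$id <- if (!is.null(genes$ID)) as.character(genes$ID) else
      paste0("gene", seq_along(genes))
  }
  te_types <- c("transposable_element", "TE", "repeat_region")
  tes <- gff[types %in% te_types]
  if (!is.null(te_path)) {
    fmt <- if (grepl("\\.bed(\\.gz)?$", te_path)) "bed" else "gff3"
    tes <- rtracklayer::import(te_path, format = fmt)
  }
  if (length(tes)) {
    te_id <- if (!is.null(tes$ID)) as.character(tes$ID) else
      if (!is.null(tes$name)) as.character(tes$name) else
        paste0("te", seq_along(tes))
    S4Vectors::mcols(tes) <- NULL
    tes$id <- te_id
  }
  if (length(genes)) S4Vectors::mcols(genes) <- S4Vectors::DataFrame(id = genes$id)
  if (is.null(chloroplast_name)) {
    chloroplast_name <- if ("chloroplast" %in% names(seqlengths))
      "chloroplast" else NA_character_
  }
  annotation_set(genes, tes, seqlengths, chloroplast_name)
}

#' Read accessibility intervals from BED
#'
#' @param bed_path BED file of accessible-chromatin intervals (e.g. DNase I
#'   hypersensitive sites).
#' @return A `GRanges`.
#' @export
read_accessibility <- function(bed_path) {
  rtracklayer::import(bed_path, format = "bed")
}
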