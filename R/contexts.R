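#' Classify a cytosine trinucleotide into its methylation context
#'
#' Plant cytosine methylation is tracked in three sequence contexts derived
#' from the trinucleotide starting at the cytosine on its own strand:
#' CG when the second base is G, CHG when the third (but not the second) base
#' is G, and CHH otherwise (H = A, C or T).
#'
#' @param trinucleotide Character vector of 3-mers on the cytosine's strand,
#'   e.g. `"CAA"`. The first base must be `C` and all bases in `A,C,G,T`.
#' @return Character vector of the same length with values `"CG"`, `"CHG"`
#'   or `"CHH"`.
#' @examples
#' classify_subcontext(c("CGA", "CCG", "CAA"))
#' @export
classify_subcontext <- function(trinucleotide) {
  tri <- toupper(as.character(trinucleotide))
  bad_len <- nchar(tri) != 3L
  if (any(bad_len, na.rm = TRUE) || anyNA(tri)) {
    stop("trinucleotides must be 3-mers, got: ",
         paste(unique(tri[bad_len | is.na(tri)]), collapse = ", "))
  }
  if (!all(grepl("^[ACGT]{3}$", tri))) {
    stop("ambiguous or invalid base in trinucleotide(s): ",
         paste(unique(tri[!grepl("^[ACGT]{3}$", tri)]), collapse = ", "))
  }
  if (any(substr(tri, 1L, 1L) != "C")) {
    stop("trinucleotide(s) not starting with C: ",
         paste(unique(tri[substr(tri, 1L, 1L) != "C"]), collapse = ", "))
  }
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
}

#' All 16 C-initial trinucleotides
#' @return Character vector of the 16 trinucleotides beginning with C.
#' @export
c_trinucleotides <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(outer(bases, bases, function(b2, b3) paste0("C", b2, b3)))
}
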