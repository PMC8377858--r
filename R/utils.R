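#' @keywords internal
"_PACKAGE"

#' @useDynLib pegforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor predict rnorm runif setNames sd quantile
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; input must be uppercase ACGT.
#'
#' @param x character scalar, DNA.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Convert DNA to RNA alphabet
#' @param x character scalar, DNA.
#' @return character scalar with T replaced by U.
#' @export
dna_to_rna <- function(x) chartr("T", "U", x)

is_dna <- function(x) {
  nchar(x) >= 1L && !grepl("[^ACGT]", x)
}

#' Fraction of G or C bases
#'
#' @param seq nonempty DNA (or RNA) string.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("gc_content: empty sequence")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(b == "G" | b == "C") / length(b)
}

# substring by 0-based half-open interval [from, to)
substr0 <- function(x, from, to) {
  if (to <= from) return("")
  substr(x, from + 1L, to)
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps derived seeds inside 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
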