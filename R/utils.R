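# Small shared helpers.

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Strip a leading "chr" prefix from chromosome names
#'
#' Used to normalize chromosome naming symmetrically before joining variant
#' tables that may disagree on the prefix convention ("chr1" vs "1").
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without the "chr" prefix.
#' @export
strip_chr <- function(x) sub("^chr", "", as.character(x))

# Canonical variant key used for all per-variant joins (chrom normalized).
variant_uid <- function(chrom, pos, ref, alt) {
  paste(strip_chr(chrom), as.integer(pos), ref, alt, sep = ":")
}

DNA_BASES <- c("A", "C", "G", "T")
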