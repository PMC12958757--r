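# Shared helpers: condition signalling, sequence utilities, variant keys.

rad_abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("radspectra_", class), "radspectra_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Complement / reverse-complement of DNA strings
#'
#' Thin vectorised wrappers kept in base R (`chartr`) for scalar speed inside
#' per-variant loops; sequence-scale operations go through Biostrings.
#' @param x character vector of DNA strings (ACGT).
#' @return character vector of the same length.
#' @keywords internal
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Variant key
#'
#' Canonical `(chrom, pos, ref, alt)` key used for caller intersection,
#' frequency-panel joins and carrier maps.
#' @param df data.frame with columns chrom, pos, ref, alt.
#' @return character vector of keys.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# empty variant table with the canonical column set
empty_variants <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    vclass = character(), sample = character(), caller = character(),
    qd = numeric(), qual = numeric(), sor = numeric(), fs = numeric(),
    mq = numeric(), mqranksum = numeric(), readposranksum = numeric(),
    support_reads = integer(), stringsAsFactors = FALSE
  )
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L
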