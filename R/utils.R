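# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement without reversal (strand flips of single bases)
dna_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# round half away from zero; base round() is half-to-even
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# normalize a mature miRNA sequence to the RNA alphabet (T -> U), validate
normalize_rna <- function(seq) {
  s <- chartr("tT", "uU", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    stop("sequence contains characters outside the RNA alphabet (ACGU): ",
         paste(unique(seq[bad]), collapse = ", "))
  }
  s
}

check_dna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x))) {
    stop(what, " contains characters outside the DNA alphabet (ACGT)")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
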