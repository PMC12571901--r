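#' Reverse complement of a DNA string
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors (DNA alphabet, `T` not `U`).
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACAATTATGTC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

## mRNA coordinates have no position 0: +1 is the A of the start codon and
## -1 the base immediately 5' of it.  Internally we work on a continuous
## integer axis where +1 -> 1 and -1 -> 0.
off2idx <- function(o) ifelse(o > 0, o, o + 1L)
idx2off <- function(i) ifelse(i >= 1, i, i - 1L)

## span of a zeroless window, e.g. -37..+44 -> 81
window_span <- function(from, to) off2idx(to) - off2idx(from) + 1L

normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

assert_dna <- function(seq, allow_n = TRUE, arg = "seq") {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    abort(sprintf("`%s` contains characters outside the %s alphabet: %s",
                  arg, if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}",
                  paste(head(seq[bad], 3), collapse = ", ")))
  }
  invisible(seq)
}
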