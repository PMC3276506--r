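#' Linear DNA genome
#'
#' A `genome` is a named linear DNA sequence over the alphabet `A`, `C`, `G`,
#' `T`, `N`, addressed with 1-based inclusive coordinates throughout the
#' package.  Lowercase input is uppercased and `U` is normalised to `T`.
#'
#' @param id Non-empty record identifier.
#' @param seq DNA sequence as a single string.
#' @return An object of class `genome` with fields `id`, `seq` and
#'   `topology` (always `"linear"`).
#' @examples
#' g <- genome("toy", "acgtACGT")
#' genome_length(g)
#' @export
genome <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("genome id must be a single non-empty string")
  seq <- normalize_dna(seq, context = sprintf("genome '%s'", id))
  structure(list(id = id, seq = seq, topology = "linear"), class = "genome")
}

# Uppercase, U->T, and reject anything outside {A,C,G,T,N}.
normalize_dna <- function(seq, context = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(sprintf("%s must be a single string", context))
  seq <- chartr("U", "T", toupper(seq))
  if (nchar(seq) < 1L) stop(sprintf("%s is empty", context))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(sprintf("non-DNA characters in %s: '%s'", context,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  seq
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp linear\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Genome length in base pairs
#' @param g A [genome].
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$seq)

#' 1-based inclusive interval on a genome
#'
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `interval`.
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("interval requires 1 <= start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval> %d..%d (%s)\n", x$start, x$end, x$strand))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param s DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement, same alphabet.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a subsequence
#'
#' Returns the bases of `g` covered by `iv`; for strand `"-"` the reverse
#' complement is returned.
#'
#' @param g A [genome].
#' @param iv An [interval] within the genome bounds.
#' @return DNA string of length `end - start + 1`.
#' @export
subsequence <- function(g, iv) {
  L <- genome_length(g)
  if (iv$end > L)
    stop(sprintf("interval end %d exceeds genome '%s' length %d",
                 iv$end, g$id, L))
  s <- substr(g$seq, iv$start, iv$end)
  if (iv$strand == "-") s <- revcomp(s)
  s
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param dna In-frame DNA string; length must be divisible by 3.
#' @return Protein string; stop codons are rendered as `*`.
#' @export
translate_cds <- function(dna) {
  dna <- normalize_dna(dna, "coding sequence")
  if (nchar(dna) %% 3L != 0L)
    stop(sprintf("coding sequence length %d is not divisible by 3", nchar(dna)))
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "X"))
}
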