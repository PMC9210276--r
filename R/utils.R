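#' @import Biostrings
#' @importFrom stats runif setNames aggregate sd rgeom
#' @importFrom utils write.table read.table capture.output
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# transition partner of each base
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# IUPAC code for a sorted set of bases
IUPAC_OF <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x A single DNA character string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence at a given GC content
#'
#' Draws i.i.d. nucleotides; uses the current R RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param n Length in bp.
#' @param gc GC content, a fraction in (0, 1).
#' @return A character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.4) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

# split a string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# Deterministic per-stage RNG substream: a small string hash folded into the
# master seed, kept below 2^31.
substream_seed <- function(seed, stream) {
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) + h) %% 2147483647L)
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(as.character(set), names(set))
}

#' Translate a nucleotide string in frame 1
#'
#' Incomplete trailing codons are dropped; codons containing non-ACGT
#' characters translate to `X`. Stop codons appear as `*`.
#'
#' @param x DNA character string.
#' @return Amino-acid character string.
#' @export
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

comp_base <- function(x) unname(COMP[x])

# pick a base different from `forbidden` (keeps `current` when already fine);
# deterministic so generator output depends only on the RNG stream
guard_base <- function(current, forbidden) {
  if (is.na(forbidden) || current != forbidden) return(current)
  DNA_BASES4[match(forbidden, DNA_BASES4) %% 4L + 1L]
}

# interval helpers: 1-based closed intervals as c(start, end)
interval_len <- function(iv) iv[2] - iv[1] + 1L

jaccard_interval <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  uni <- interval_len(a) + interval_len(b) - inter
  inter / uni
}
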