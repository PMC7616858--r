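# Low-level nucleotide-string helpers. Sequences are plain uppercase character
# strings throughout; Biostrings objects are only materialised at the FASTA
# boundary. All coordinates in the package are 1-based inclusive.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters other than A/C/G/T/N", what))
  }
  invisible(x)
}

# does each single base in `bases` fall in the IUPAC class of `code`?
iupac_base_match <- function(bases, code) {
  allowed <- IUPAC_SETS[[code]]
  if (is.null(allowed)) abort(sprintf("unknown IUPAC code '%s'", code))
  bases %in% allowed
}

# vectorised match of fixed-length strings against an IUPAC pattern
iupac_match <- function(x, pattern) {
  stopifnot(all(nchar(x) == nchar(pattern)))
  codes <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(x))
  for (i in seq_along(codes)) {
    ok <- ok & iupac_base_match(substr(x, i, i), codes[i])
  }
  ok
}

#' Translate a coding sequence
#'
#' Standard genetic code; a trailing stop codon is represented as `"*"`.
#'
#' @param cds_seq Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string (single-letter code, `*` for stop).
#' @examples
#' translate_dna("ATGGCATGTTAA")
#' @export
translate_dna <- function(cds_seq) {
  stopifnot(is.character(cds_seq), length(cds_seq) == 1)
  n <- nchar(cds_seq)
  if (n %% 3 != 0) {
    abort(sprintf("coding sequence length %d not divisible by 3", n))
  }
  if (n == 0) return("")
  codons <- substring(cds_seq, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1]
    abort(sprintf("ambiguous or invalid codon '%s' at codon %d",
                  codons[bad], bad))
  }
  paste(aa, collapse = "")
}

# random DNA helpers used by the simulator
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  !grepl("[^ACGT]", names(Biostrings::GENETIC_CODE))
], c("TAA", "TAG", "TGA"))

random_orf <- function(n_codons) {
  # ATG ... sense codons ... TAA; length n_codons includes start and stop
  stopifnot(n_codons >= 3)
  body <- sample(SENSE_CODONS, n_codons - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}
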