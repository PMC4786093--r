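# Core sequence container and genetic-code helpers.

# Standard (bacterial table 11 differs only in initiation; elongation-level
# translation is identical to table 1, which is what matters here).
.genetic_code <- function() Biostrings::GENETIC_CODE

.stop_codons <- function() names(.genetic_code())[.genetic_code() == "*"]

.sense_codons <- function() names(.genetic_code())[.genetic_code() != "*"]

# amino acid one-letter <-> three-letter lookup
.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val")

#' Normalize an amino-acid label to the one-letter code
#'
#' Accepts one-letter (`"L"`) or three-letter (`"Leu"`, case-insensitive)
#' amino-acid labels.
#'
#' @param aa character vector of amino-acid labels.
#' @return character vector of one-letter codes.
#' @export
aa_one_letter <- function(aa) {
  aa <- as.character(aa)
  out <- character(length(aa))
  three <- names(.aa3)[match(tolower(aa), tolower(.aa3))]
  one <- toupper(aa)
  ok1 <- nchar(aa) == 1L & one %in% names(.aa3)
  out[ok1] <- one[ok1]
  out[!ok1] <- three[!ok1]
  if (anyNA(out) || any(out == ""))
    stop("unknown amino acid label(s): ",
         paste(aa[is.na(out) | out == ""], collapse = ", "))
  out
}

#' Convert codons between DNA and RNA alphabets
#'
#' Sequences are held internally in the DNA alphabet; outputs use the RNA
#' alphabet, the convention of the codon-usage literature.
#'
#' @param x character vector of codons or sequences.
#' @return character vector with T/U exchanged.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname as_rna
#' @export
as_dna <- function(x) toupper(chartr("Uu", "Tt", x))

#' Create a coding sequence
#'
#' An in-frame protein-coding sequence. Input may be DNA or RNA, any case;
#' it is normalized to uppercase DNA. The sequence must be a whole number of
#' codons and must not contain an internal stop codon (a terminal stop is
#' allowed and is excluded from codon-level editing and counting of sense
#' codons).
#'
#' @param id character scalar, sequence identifier.
#' @param seq character scalar, nucleotide sequence over A/C/G/T/U.
#' @return an object of class `coding_sequence` with elements `id` and `seq`.
#' @examples
#' cds <- coding_sequence("toy", "ATGTTATAA")
#' codons(cds)
#' translate_cds(cds)
#' @export
coding_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- as_dna(seq)
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) > 0L)
    stop(sprintf("sequence '%s': ambiguous or invalid nucleotide '%s' at position %d",
                 id, bad, regexpr("[^ACGT]", seq)))
  if (nchar(seq) %% 3L != 0L)
    stop(sprintf("sequence '%s': length %d is not divisible by 3 (frame error)",
                 id, nchar(seq)))
  if (nchar(seq) < 3L)
    stop(sprintf("sequence '%s' is empty", id))
  x <- structure(list(id = id, seq = seq), class = "coding_sequence")
  cod <- codons(x)
  gc <- .genetic_code()
  internal <- cod[-length(cod)]
  if (any(gc[internal] == "*"))
    stop(sprintf("sequence '%s': internal stop codon at codon %d",
                 id, which(gc[internal] == "*")[1L]))
  x
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons)\n",
              x$id, nchar(x$seq), nchar(x$seq) %/% 3L))
  invisible(x)
}

#' Split a coding sequence into codons
#'
#' @param x a `coding_sequence` (or an in-frame nucleotide string).
#' @return character vector of consecutive non-overlapping triplets (DNA).
#' @export
codons <- function(x) {
  seq <- if (inherits(x, "coding_sequence")) x$seq else as_dna(x)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Number of codons in a coding sequence
#' @param x a `coding_sequence`.
#' @return integer codon count (including a terminal stop if present).
#' @export
n_codons <- function(x) nchar(x$seq) %/% 3L

#' Translate a coding sequence
#'
#' @param x a `coding_sequence`.
#' @return single character string of one-letter amino acids; a terminal stop
#'   is rendered as `"*"`.
#' @export
translate_cds <- function(x) {
  paste(.genetic_code()[codons(x)], collapse = "")
}
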