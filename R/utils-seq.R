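# Sequence utilities shared across modules. Sequences travel as plain
# character vectors; files are DNA (T), in-memory miRNA work is RNA (U).

#' Convert nucleotide strings to RNA (T -> U) or DNA (U -> T)
#'
#' Case is normalized to upper. Both functions accept either alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in the requested alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "TT", toupper(x))

#' Reverse complement of nucleotide sequences
#'
#' Operates in the alphabet of the input: an RNA input returns RNA.
#'
#' @param x character vector of sequences over A/C/G/T/U/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE)
  d <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(x))))
  ifelse(is_rna, as_rna(d), d)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Random DNA strings; relies on the caller having seeded the RNG.
random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) paste(sample(alphabet, l, replace = TRUE),
                                collapse = ""), character(1))
}

validate_nucleotides <- function(x, alphabet = "ACGUTN", what = "sequence") {
  bad <- grepl(sprintf("[^%s]", alphabet), toupper(x))
  if (any(bad)) {
    stop(sprintf("non-nucleotide characters in %s: %s", what,
                 paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Largest-remainder apportionment of counts
#'
#' Splits `total` into integer counts proportional to `fracs` such that the
#' counts sum exactly to `total`. Floors first, then hands remaining units
#' to the largest fractional parts (ties broken by position). Used by the
#' synthetic read generator so per-category count assertions are exact.
#'
#' @param fracs non-negative numeric vector of fractions (need not be
#'   normalized).
#' @param total integer total to apportion.
#' @return integer vector, same names as `fracs`, summing to `total`.
#' @export
largest_remainder <- function(fracs, total) {
  stopifnot(all(fracs >= 0), total >= 0)
  share <- fracs / sum(fracs) * total
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(fracs)
  counts
}

# Mean Phred score of a Sanger-encoded quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}

phred_string <- function(phred, len) {
  vapply(len, function(l) paste(rep(intToUtf8(phred + 33L), l),
                                collapse = ""), character(1))
}
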