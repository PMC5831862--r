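# File formats: FASTQ (Sanger), FASTA, GMT. FASTA goes through Biostrings;
# FASTQ uses a strict 4-line reader so malformed records can be reported
# with their record index (a contract Biostrings does not expose).

#' Read a 4-line FASTQ file
#'
#' @param path path to an uncompressed Sanger-quality FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) stop("empty FASTQ file: ", path)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ record %d in %s: truncated record",
                 n %/% 4L + 1L, path))
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s: bad header/separator",
                 bad[1], path))
  }
  bad <- which(nchar(seq) != nchar(qual) | nchar(seq) == 0L)
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s: sequence/quality mismatch",
                 bad[1], path))
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = toupper(seq), qual = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read/write FASTA as a named character vector
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), as_dna(seqs))), path)
  invisible(path)
}

#' Read/write GMT gene-set collections
#'
#' GMT: one set per line, tab-separated: name, description, genes...
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1], " in ", path)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[`, character(1), 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  writeLines(mapply(function(nm, ds, gs) {
    paste(c(nm, ds, gs), collapse = "\t")
  }, names(sets), descriptions, sets), path)
  invisible(path)
}
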