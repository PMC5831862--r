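# Raw small RNA read cleaning. Filters are applied in a fixed order and a
# removed read is attributed to the FIRST failing filter:
#   1 poly_n                any N (or >= max_n Ns when max_n > 1)
#   2 adapter5_contaminant  read prefix matches the 5' adapter
#   3 no_adapter3           no 3' adapter hit; hits are trimmed
#   4 homopolymer           post-trim single-base fraction >= homopolymer_frac
#   5 low_quality           mean Phred below min_mean_q (skipped for FASTA)
#   6 length                post-trim length outside [min_len, max_len]

#' Parameters for small RNA read filtering
#'
#' Thresholds follow common small RNA practice and are all overridable:
#' any N removes a read (`max_n = 1`), adapters are located by
#' prefix-suffix overlap of at least `min_adapter_overlap` bases with at
#' most `adapter_mismatches` mismatches, post-trim pure homopolymers are
#' dropped (`homopolymer_frac = 1`), mean Phred must reach `min_mean_q`,
#' and inserts must fall in `[min_len, max_len]` (default 18-32 nt).
#'
#' @param max_n remove reads with at least this many N bases.
#' @param adapter_mismatches maximum mismatches in an adapter match.
#' @param min_adapter_overlap minimum read/adapter overlap length.
#' @param homopolymer_frac single-base fraction at or above which a trimmed
#'   read counts as a homopolymer (1 = pure poly-A/T/G/C only).
#' @param min_mean_q minimum mean Phred quality.
#' @param min_len,max_len allowed post-trim insert length range.
#' @param require_adapter3 when `FALSE`, reads without a 3' adapter hit
#'   are kept untrimmed instead of removed (for re-filtering already
#'   trimmed inserts, where filtering is then idempotent).
#' @return a named list of class `qc_params`.
#' @export
qc_params <- function(max_n = 1L, adapter_mismatches = 1L,
                      min_adapter_overlap = 6L, homopolymer_frac = 1.0,
                      min_mean_q = 20, min_len = 18L, max_len = 32L,
                      require_adapter3 = TRUE) {
  p <- list(max_n = as.integer(max_n),
            adapter_mismatches = as.integer(adapter_mismatches),
            min_adapter_overlap = as.integer(min_adapter_overlap),
            homopolymer_frac = homopolymer_frac,
            min_mean_q = min_mean_q,
            min_len = as.integer(min_len), max_len = as.integer(max_len),
            require_adapter3 = isTRUE(require_adapter3))
  stopifnot(p$homopolymer_frac > 0, p$homopolymer_frac <= 1,
            p$min_len >= 1, p$max_len >= p$min_len)
  class(p) <- "qc_params"
  p
}

#' Locate the 3' adapter in a read
#'
#' Scans every start position; the adapter may run off the read end
#' (prefix-suffix overlap). A position qualifies when the overlap is at
#' least `min_overlap` and has at most `max_mismatch` mismatches over the
#' whole overlap. Among qualifying positions the one with fewest
#' mismatches wins; ties go to the longest overlap (leftmost start).
#'
#' @param seq read sequence (DNA, character scalar).
#' @param adapter adapter sequence.
#' @param min_overlap,max_mismatch match thresholds.
#' @return 1-based start of the adapter match, or `NA_integer_`.
#' @export
locate_adapter <- function(seq, adapter, min_overlap = 6L,
                           max_mismatch = 1L) {
  len <- nchar(seq)
  alen <- nchar(adapter)
  last_start <- len - min_overlap + 1L
  if (last_start < 1L) return(NA_integer_)
  best <- NA_integer_
  best_mm <- max_mismatch + 1L
  for (start in seq_len(last_start)) {
    ov <- min(alen, len - start + 1L)
    mm <- hamming(substr(seq, start, start + ov - 1L),
                  substr(adapter, 1L, ov))
    if (mm <= max_mismatch && mm < best_mm) {
      best <- start
      best_mm <- mm
      if (mm == 0L) break  # leftmost perfect match also has longest overlap
    }
  }
  best
}

#' Filter raw small RNA reads
#'
#' Applies the poly-N, 5'-adapter-contaminant, 3'-adapter, homopolymer,
#' quality and length filters in fixed order (see source header), trimming
#' the 3' adapter from retained reads. Each removed read is attributed to
#' the first failing filter, so per-filter counts plus the clean count
#' always equal the input count.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (as from [read_fastq()]); FASTA input may omit `qual`.
#' @param adapter_3p 3' adapter sequence (required, non-empty).
#' @param adapter_5p optional 5' adapter; when `NULL` filter 2 is a no-op.
#' @param params a [qc_params()] list.
#' @return list of class `qc_result`: `clean` (data.frame of trimmed
#'   reads), `report` (total, removed_per_filter, clean_reads,
#'   length_histogram, base_frequency).
#' @export
filter_reads <- function(reads, adapter_3p, adapter_5p = NULL,
                         params = qc_params()) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (!nzchar(adapter_3p)) stop("adapter_3p must be non-empty")
  adapter_3p <- as_dna(adapter_3p)
  seqs <- as_dna(reads$seq)
  has_qual <- "qual" %in% names(reads) && !all(is.na(reads$qual))
  n <- length(seqs)
  filters <- c("poly_n", "adapter5_contaminant", "no_adapter3",
               "homopolymer", "low_quality", "length")
  fate <- rep(NA_character_, n)  # NA = still alive

  # 1: poly-N
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  fate[is.na(fate) & n_count >= params$max_n] <- "poly_n"

  # 2: 5' adapter contaminant (prefix match)
  if (!is.null(adapter_5p) && nzchar(adapter_5p)) {
    adapter_5p <- as_dna(adapter_5p)
    a5 <- vapply(seqs, function(s) {
      ov <- min(nchar(adapter_5p), nchar(s))
      ov >= params$min_adapter_overlap &&
        hamming(substr(s, 1L, ov), substr(adapter_5p, 1L, ov)) <=
          params$adapter_mismatches
    }, logical(1), USE.NAMES = FALSE)
    fate[is.na(fate) & a5] <- "adapter5_contaminant"
  }

  # 3: locate + trim 3' adapter
  trimmed <- seqs
  alive <- which(is.na(fate))
  pos <- vapply(seqs[alive], locate_adapter, integer(1),
                adapter = adapter_3p,
                min_overlap = params$min_adapter_overlap,
                max_mismatch = params$adapter_mismatches,
                USE.NAMES = FALSE)
  if (params$require_adapter3) fate[alive[is.na(pos)]] <- "no_adapter3"
  hit <- alive[!is.na(pos)]
  trimmed[hit] <- substr(seqs[hit], 1L, pos[!is.na(pos)] - 1L)
  # an adapter match at position 1 leaves an empty insert -> length filter
  # territory, but attribute to no_adapter3 when there is no insert at all
  empty <- hit[nchar(trimmed[hit]) == 0L]
  fate[empty] <- "no_adapter3"

  # 4: post-trim homopolymer
  alive <- which(is.na(fate))
  homo <- vapply(trimmed[alive], function(s) {
    tab <- table(strsplit(s, "")[[1]])
    max(tab) / nchar(s) >= params$homopolymer_frac
  }, logical(1), USE.NAMES = FALSE)
  fate[alive[homo]] <- "homopolymer"

  # 5: low quality (mean Phred over the untrimmed read)
  if (has_qual) {
    alive <- which(is.na(fate))
    lowq <- mean_phred(reads$qual[alive]) < params$min_mean_q
    fate[alive[lowq]] <- "low_quality"
  }

  # 6: post-trim length window
  alive <- which(is.na(fate))
  ln <- nchar(trimmed[alive])
  fate[alive[ln < params$min_len | ln > params$max_len]] <- "length"

  keep <- which(is.na(fate))
  clean <- data.frame(id = reads$id[keep], seq = trimmed[keep],
                      stringsAsFactors = FALSE)
  if (has_qual) {
    clean$qual <- substr(reads$qual[keep], 1L, nchar(clean$seq))
  }
  removed <- vapply(filters, function(f) sum(fate == f, na.rm = TRUE),
                    integer(1))
  report <- list(
    total_reads = n,
    removed_per_filter = removed,
    clean_reads = length(keep),
    length_histogram = if (length(keep)) length_distribution(clean$seq)
                       else integer(0),
    base_frequency = if (length(keep)) first_base_profile(clean$seq)
                     else NULL)
  stopifnot(report$clean_reads + sum(removed) == n)
  structure(list(clean = clean, report = report, fate = fate),
            class = "qc_result")
}

#' Length histogram of clean reads
#'
#' @param seqs character vector of sequences (at least one).
#' @return named integer vector: counts by length, ascending.
#' @export
length_distribution <- function(seqs) {
  if (length(seqs) == 0L) stop("no reads: cannot compute length histogram")
  tab <- table(nchar(seqs))
  setNames(as.integer(tab), names(tab))
}

#' Per-position base frequency profile
#'
#' Column j is computed over reads of length at least j, so every column
#' sums to 1. Frequencies are reported in the RNA alphabet (T counted
#' as U).
#'
#' @param seqs character vector of sequences (at least one).
#' @param L number of positions (default: longest read).
#' @return 4 x L matrix, rows A/C/G/U, columns summing to 1.
#' @export
first_base_profile <- function(seqs, L = max(nchar(seqs))) {
  if (length(seqs) == 0L) stop("no reads: cannot compute base profile")
  seqs <- as_rna(seqs)
  bases <- c("A", "C", "G", "U")
  mat <- matrix(0, nrow = 4L, ncol = L, dimnames = list(bases, seq_len(L)))
  chars <- strsplit(seqs, "")
  for (cs in chars) {
    jj <- seq_len(min(length(cs), L))
    for (j in jj) {
      b <- cs[[j]]
      if (b %in% bases) mat[b, j] <- mat[b, j] + 1
    }
  }
  sweep(mat, 2L, colSums(mat), "/")
}
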