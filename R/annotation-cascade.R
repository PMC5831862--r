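# Annotation-based read classification. A clean read is assigned to the
# highest-priority annotation category in which it occurs as an exact
# full-length substring (0 mismatches); exon/intron categories are matched
# on both strands with the strand recorded. Unmatched reads are "other".

.ANNOT_CATEGORIES <- c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                       "repeat", "exon", "intron")
.STRANDED_CATEGORIES <- c("exon", "intron")

#' Build an annotation index from per-category reference sequences
#'
#' @param references named list; each element a (named) character vector of
#'   reference sequences for one category. Allowed categories:
#'   known_miRNA, rRNA, tRNA, snRNA, snoRNA, repeat, exon, intron.
#' @param priority character vector giving the match priority (highest
#'   first); defaults to the allowed-category order with known_miRNA
#'   first. Must be a permutation of the configured categories.
#' @return object of class `annotation_index`.
#' @export
annotation_index <- function(references, priority = NULL) {
  stopifnot(is.list(references), !is.null(names(references)))
  bad <- setdiff(names(references), .ANNOT_CATEGORIES)
  if (length(bad)) {
    stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  }
  if (is.null(priority)) {
    priority <- intersect(.ANNOT_CATEGORIES, names(references))
  }
  if (!setequal(priority, names(references)) ||
      length(priority) != length(references)) {
    stop("priority must be a permutation of the configured categories")
  }
  refs <- lapply(references, as_dna)
  structure(list(references = refs, priority = priority,
                 # one subject string per category; '\n' cannot occur in a
                 # read so matches never span reference boundaries
                 subjects = vapply(refs, paste, character(1),
                                   collapse = "\n")),
            class = "annotation_index")
}

#' Build an annotation index from GFF3 intervals plus a genome FASTA
#'
#' Extracts the sequence under each interval of the requested feature
#' types (1-based inclusive GFF3 coordinates) and builds the same index as
#' [annotation_index()]. Requires the rtracklayer package for GFF3 import.
#'
#' @param gff_path GFF3 file.
#' @param genome named character vector of genome sequences (as from
#'   [read_fasta()]) or a path to a genome FASTA.
#' @param feature_categories named character vector mapping GFF3 feature
#'   types to annotation categories, e.g. `c(exon = "exon")`.
#' @param priority passed to [annotation_index()].
#' @return object of class `annotation_index`.
#' @export
annotation_index_from_gff <- function(gff_path, genome,
                                      feature_categories =
                                        c(exon = "exon", intron = "intron"),
                                      priority = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("annotation_index_from_gff requires the rtracklayer package")
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% names(feature_categories)]
  refs <- list()
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    if (!chrom %in% names(genome)) {
      stop("GFF3 interval on unknown sequence: ", chrom)
    }
    st <- GenomicRanges::start(gr[i])
    en <- GenomicRanges::end(gr[i])
    if (st < 1L || en > nchar(genome[[chrom]])) {
      stop(sprintf("GFF3 interval outside genome bounds: %s:%d-%d",
                   chrom, st, en))
    }
    cat <- feature_categories[[as.character(gr[i]$type)]]
    seq <- substr(genome[[chrom]], st, en)
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (strand == "-") seq <- revcomp(seq)
    refs[[cat]] <- c(refs[[cat]], seq)
  }
  annotation_index(refs, priority = priority)
}

#' Classify clean reads against an annotation index
#'
#' Exact full-length substring matching, highest-priority category wins;
#' exon/intron matches record the strand (`exon:+` / `exon:-`). Reads
#' matching nothing are labeled `other`.
#'
#' @param reads character vector of clean read sequences (DNA or RNA), or
#'   a data.frame with a `seq` column.
#' @param index an [annotation_index()].
#' @return list of class `classification`: `labels` (per-read), `report`
#'   (per-category counts, mapped_total, removed_total, remaining).
#' @export
classify_reads <- function(reads, index) {
  stopifnot(inherits(index, "annotation_index"))
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0L) stop("no reads to classify")
  seqs <- as_dna(reads)
  labels <- rep("other", length(seqs))
  undecided <- rep(TRUE, length(seqs))
  rc <- NULL
  for (cat in index$priority) {
    if (!any(undecided)) break
    subj <- index$subjects[[cat]]
    idx <- which(undecided)
    hit_sense <- vapply(seqs[idx], grepl, logical(1), x = subj,
                        fixed = TRUE, USE.NAMES = FALSE)
    if (cat %in% .STRANDED_CATEGORIES) {
      if (is.null(rc)) rc <- revcomp(seqs)
      hit_anti <- vapply(rc[idx], grepl, logical(1), x = subj,
                         fixed = TRUE, USE.NAMES = FALSE)
      labels[idx[hit_sense]] <- paste0(cat, ":+")
      labels[idx[!hit_sense & hit_anti]] <- paste0(cat, ":-")
      undecided[idx[hit_sense | hit_anti]] <- FALSE
    } else {
      labels[idx[hit_sense]] <- cat
      undecided[idx[hit_sense]] <- FALSE
    }
  }
  base <- sub(":.*$", "", labels)
  counts <- table(factor(labels, levels = sort(unique(labels))))
  mapped <- sum(base != "other")
  removed <- sum(!base %in% c("known_miRNA", "other"))
  report <- list(counts = setNames(as.integer(counts), names(counts)),
                 mapped_total = mapped,
                 removed_total = removed,
                 remaining = length(seqs) - removed)
  structure(list(labels = labels, report = report),
            class = "classification")
}

#' Remove annotated non-miRNA reads and report the bookkeeping triple
#'
#' Either pass per-read `labels` from [classify_reads()] or the explicit
#' `mapped` and `removed` totals as printed in a sequencing report. The
#' bookkeeping convention is `remaining = mapped - removed` restricted to
#' mapped reads; the candidate set kept for miRNA analysis is the reads
#' labeled `known_miRNA` plus the unannotated (`other`) reads.
#'
#' @param labels per-read category labels (optional).
#' @param mapped,removed explicit totals (optional, override labels).
#' @return list: `mapped`, `removed`, `remaining`, and (when labels are
#'   given) `candidates` — indices of retained reads.
#' @export
remove_annotated <- function(labels = NULL, mapped = NULL, removed = NULL) {
  candidates <- NULL
  if (!is.null(labels)) {
    base <- sub(":.*$", "", labels)
    if (is.null(mapped)) mapped <- sum(base != "other")
    if (is.null(removed)) {
      removed <- sum(!base %in% c("known_miRNA", "other"))
    }
    candidates <- which(base %in% c("known_miRNA", "other"))
  }
  if (is.null(mapped) || is.null(removed)) {
    stop("provide labels, or both mapped and removed")
  }
  if (removed > mapped) stop("removed cannot exceed mapped")
  list(mapped = mapped, removed = removed, remaining = mapped - removed,
       candidates = candidates)
}
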