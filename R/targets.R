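# miRNA-target integration: combine two predictor tables with expression
# anti-correlation, a built-in seed-match site scanner, network export,
# and hypergeometric over-representation analysis.

#' Find seed-match sites in a 3'-UTR
#'
#' Reports every UTR heptamer that is the reverse complement of miRNA
#' positions `seed_start..seed_end` (default 2-8; Watson-Crick pairing
#' only, no G:U wobble).
#'
#' @param mirna mature miRNA sequence (RNA or DNA).
#' @param utr 3'-UTR sequence (length >= seed length).
#' @param seed_start,seed_end seed positions within the miRNA (1-based).
#' @return data.frame: `start` (0-based), `end` (half-open), `type`,
#'   `site` (matched UTR subsequence). Zero rows when no site exists.
#' @export
seed_sites <- function(mirna, utr, seed_start = 2L, seed_end = 8L) {
  validate_nucleotides(mirna, alphabet = "ACGUT", what = "miRNA")
  validate_nucleotides(utr, alphabet = "ACGUT", what = "UTR")
  if (nchar(utr) < seed_end - seed_start + 1L) {
    stop("UTR shorter than the seed")
  }
  seed <- substr(as_rna(mirna), seed_start, seed_end)
  if (nchar(seed) < seed_end - seed_start + 1L) {
    stop("miRNA shorter than the seed region")
  }
  site <- as_dna(revcomp(seed))     # scan in DNA space
  subject <- as_dna(utr)
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(site, substr(subject, from, nchar(subject)),
                 fixed = TRUE)
    if (p == -1L) break
    hits <- c(hits, from + p - 1L)
    from <- from + p  # overlapping occurrences allowed
    if (from > nchar(subject)) break
  }
  w <- nchar(site)
  data.frame(start = hits - 1L, end = hits - 1L + w,
             type = rep(sprintf("%dmer", w), length(hits)),
             site = if (length(hits)) substring(subject, hits,
                                                hits + w - 1L)
                    else character(0),
             stringsAsFactors = FALSE)
}

#' Integrate two target-prediction tables with expression anti-correlation
#'
#' A (miRNA, gene) pair is kept when it is predicted by both tables
#' (evidence `overlap`) or predicted by table A with Pearson correlation
#' between the miRNA and gene stage profiles below `max_r` (evidence
#' `anti_correlation`; `both` when the two clauses fire together). The
#' correlation clause is restricted to table A by default, mirroring
#' pipelines where only one predictor's calls are correlation-filtered;
#' set `symmetric = TRUE` to apply it to table B as well. Duplex free
#' energy is carried over from table A when present.
#'
#' @param table_a,table_b data.frames with columns `mirna`, `gene`,
#'   optionally `score` and (table A) `energy` (kcal/mol, <= 0).
#' @param mirna_profiles,gene_profiles numeric matrices (rows named by
#'   miRNA / gene, columns = stages in identical order).
#' @param max_r correlation threshold (default 0: strictly negative).
#' @param symmetric apply the correlation clause to B-only pairs too.
#' @return data.frame of class `target_edges`: `mirna`, `gene`,
#'   `evidence`, `correlation`, `energy`, sorted by (mirna, gene).
#' @export
integrate_targets <- function(table_a, table_b, mirna_profiles = NULL,
                              gene_profiles = NULL, max_r = 0,
                              symmetric = FALSE) {
  for (tb in list(table_a, table_b)) {
    stopifnot(is.data.frame(tb), all(c("mirna", "gene") %in% names(tb)))
    if (anyDuplicated(paste(tb$mirna, tb$gene))) {
      stop("duplicate (mirna, gene) rows in a prediction table")
    }
  }
  if ("energy" %in% names(table_a) &&
      any(table_a$energy > 0, na.rm = TRUE)) {
    stop("duplex free energies must be <= 0 kcal/mol")
  }
  key <- function(tb) paste(tb$mirna, tb$gene, sep = "\r")
  ka <- key(table_a)
  kb <- key(table_b)
  corr_ok <- !is.null(mirna_profiles) && !is.null(gene_profiles)
  if (corr_ok && ncol(mirna_profiles) < 3L) {
    warning("stage profiles shorter than 3: correlation clause disabled")
    corr_ok <- FALSE
  }
  if (corr_ok && ncol(mirna_profiles) != ncol(gene_profiles)) {
    stop("miRNA and gene profiles must share the stage order")
  }
  pair_cor <- function(m, g) {
    if (!corr_ok || !m %in% rownames(mirna_profiles) ||
        !g %in% rownames(gene_profiles)) return(NA_real_)
    x <- mirna_profiles[m, ]
    y <- gene_profiles[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  cand <- if (symmetric) {
    rbind(table_a[, c("mirna", "gene")],
          table_b[!kb %in% ka, c("mirna", "gene")])
  } else table_a[, c("mirna", "gene")]
  kc <- paste(cand$mirna, cand$gene, sep = "\r")
  in_a <- kc %in% ka
  in_b <- kc %in% kb
  r <- if (nrow(cand)) unname(mapply(pair_cor, cand$mirna, cand$gene))
       else numeric(0)
  anti <- !is.na(r) & r < max_r
  overlap <- in_a & in_b
  keep <- overlap | anti
  evidence <- ifelse(overlap & anti, "both",
                     ifelse(overlap, "overlap", "anti_correlation"))
  energy <- if ("energy" %in% names(table_a)) {
    table_a$energy[match(kc, ka)]
  } else rep(NA_real_, length(kc))
  out <- data.frame(mirna = cand$mirna, gene = cand$gene,
                    evidence = evidence, correlation = r,
                    energy = energy,
                    stringsAsFactors = FALSE)[keep, ]
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("target_edges", "data.frame")
  out
}

#' Export a miRNA-target network as a deterministic edge list
#'
#' Writes a TSV with columns mirna, gene, evidence, correlation, energy,
#' sorted by (mirna, gene); a header-only file when there are no edges.
#'
#' @param edges an [integrate_targets()] result (or compatible
#'   data.frame).
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_network <- function(edges, path) {
  cols <- c("mirna", "gene", "evidence", "correlation", "energy")
  for (cl in cols) {
    if (!cl %in% names(edges)) edges[[cl]] <- rep(NA, nrow(edges))
  }
  edges <- edges[order(edges$mirna, edges$gene), cols]
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test of each gene set's overlap with the
#' query genes, with Benjamini-Hochberg adjustment across sets. Gene sets
#' are restricted to the universe before testing.
#'
#' @param genes query gene ids (must all be in `universe`).
#' @param gene_sets named list of gene id vectors (as from
#'   [read_gmt()]).
#' @param universe background gene ids.
#' @param adjust adjustment method (default `"BH"`).
#' @return data.frame sorted by p: `set`, `overlap`, `set_size`,
#'   `n_query`, `n_universe`, `p`, `q`.
#' @export
enrich <- function(genes, gene_sets, universe, adjust = "BH") {
  universe <- unique(universe)
  genes <- unique(genes)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(genes %in% universe)) {
    stop("query genes outside the universe: ",
         paste(head(setdiff(genes, universe), 3), collapse = ", "))
  }
  N <- length(universe)
  n_draw <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(genes, set))
    m <- length(set)
    p <- phyper(k - 1, m, N - m, n_draw, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, n_query = n_draw,
               n_universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = adjust)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
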