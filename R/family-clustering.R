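# Cross-species miRNA family clustering. Two mature miRNAs match when an
# ungapped alignment with 5' offset in {-1, 0, +1} covers >= 15 nt
# including the seed region (positions 2-8) of both sequences with at most
# 2 mismatches. Families are the connected components of the match graph
# (single linkage).

#' Parameters for mature miRNA family clustering
#'
#' @param min_overlap minimum ungapped alignment length (nt).
#' @param max_mismatch maximum mismatches within the alignment.
#' @param max_offset maximum 5'-end overhang (offset range is
#'   `-max_offset..max_offset`).
#' @param seed_start,seed_end seed region positions (1-based, inclusive).
#' @param require_seed `"both"` (default, stricter reading: the alignment
#'   must cover the seed of both sequences) or `"either"`.
#' @return a named list of class `family_params`.
#' @export
family_params <- function(min_overlap = 15L, max_mismatch = 2L,
                          max_offset = 1L, seed_start = 2L, seed_end = 8L,
                          require_seed = c("both", "either")) {
  p <- list(min_overlap = as.integer(min_overlap),
            max_mismatch = as.integer(max_mismatch),
            max_offset = as.integer(max_offset),
            seed_start = as.integer(seed_start),
            seed_end = as.integer(seed_end),
            require_seed = match.arg(require_seed))
  class(p) <- "family_params"
  p
}

#' Test whether two mature miRNAs belong to the same family
#'
#' Scans ungapped alignments at 5' offsets `-max_offset..max_offset`
#' (offset = position of b's first base relative to a's). An offset passes
#' when the overlap is at least `min_overlap` nt, contains at most
#' `max_mismatch` mismatches, and covers the seed region of both (or
#' either) sequence. Among passing offsets the fewest mismatches wins,
#' ties broken in favour of offset 0.
#'
#' @param a,b sequences (RNA or DNA; U/T equivalent), length >= 15.
#' @param params a [family_params()] list.
#' @return list: `match` (logical), `offset`, `mismatches` (NA when no
#'   offset passes).
#' @export
pairwise_match <- function(a, b, params = family_params()) {
  a <- as_rna(a)
  b <- as_rna(b)
  validate_nucleotides(c(a, b), alphabet = "ACGU", what = "mature miRNA")
  la <- nchar(a)
  lb <- nchar(b)
  if (la < params$min_overlap || lb < params$min_overlap) {
    stop("sequences must be at least min_overlap (", params$min_overlap,
         ") nt long")
  }
  offsets <- c(0L, seq_len(params$max_offset), -seq_len(params$max_offset))
  offsets <- offsets[!duplicated(offsets)]
  best <- list(match = FALSE, offset = NA_integer_,
               mismatches = NA_integer_)
  best_mm <- params$max_mismatch + 1L
  for (o in offsets) {
    # a position j pairs b position j - o
    ja1 <- max(1L, 1L + o)
    ja2 <- min(la, lb + o)
    ov <- ja2 - ja1 + 1L
    if (ov < params$min_overlap) next
    cov_a <- ja1 <= params$seed_start && ja2 >= params$seed_end
    cov_b <- (ja1 - o) <= params$seed_start && (ja2 - o) >= params$seed_end
    seed_ok <- if (params$require_seed == "both") cov_a && cov_b
               else cov_a || cov_b
    if (!seed_ok) next
    mm <- hamming(substr(a, ja1, ja2), substr(b, ja1 - o, ja2 - o))
    if (mm <= params$max_mismatch && mm < best_mm) {
      best <- list(match = TRUE, offset = o, mismatches = mm)
      best_mm <- mm
      if (mm == 0L) break  # offset 0 is scanned first: tie already won
    }
  }
  best
}

#' Cluster mature miRNAs into families (single linkage)
#'
#' Families are the connected components of the [pairwise_match()] graph.
#' Family ids are the lexicographically smallest member id, so the
#' partition is independent of input order.
#'
#' @param mirnas data.frame with columns `id`, `species`, `sequence`.
#' @param params a [family_params()] list.
#' @return list of class `family_partition`: `families` (named list of
#'   member ids), `membership` (per-miRNA family id, named by miRNA id),
#'   `species` (named list of per-family species sets), `mirnas`.
#' @export
build_families <- function(mirnas, params = family_params()) {
  stopifnot(is.data.frame(mirnas),
            all(c("id", "species", "sequence") %in% names(mirnas)),
            nrow(mirnas) >= 1L, !anyDuplicated(mirnas$id))
  n <- nrow(mirnas)
  seqs <- as_rna(mirnas$sequence)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (find(i) == find(j)) next
        if (pairwise_match(seqs[i], seqs[j], params)$match) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  fam_ids <- vapply(comp, function(ix) min(mirnas$id[ix]), character(1))
  ord <- order(fam_ids)
  comp <- comp[ord]
  fam_ids <- fam_ids[ord]
  families <- setNames(lapply(comp, function(ix) sort(mirnas$id[ix])),
                       fam_ids)
  membership <- setNames(rep(fam_ids, lengths(comp)),
                         unlist(lapply(comp, function(ix) mirnas$id[ix])))
  membership <- membership[mirnas$id]
  species <- setNames(lapply(comp, function(ix)
    sort(unique(mirnas$species[ix]))), fam_ids)
  structure(list(families = families, membership = membership,
                 species = species, mirnas = mirnas),
            class = "family_partition")
}

#' Presence/absence matrix of families across species
#'
#' @param partition a [build_families()] result.
#' @param species_list column order; every miRNA's species must appear
#'   here. Species that contributed no miRNAs give all-zero columns.
#' @return binary integer matrix, rows = family ids, columns = species.
#' @export
presence_absence <- function(partition, species_list) {
  stopifnot(inherits(partition, "family_partition"))
  missing <- setdiff(unique(partition$mirnas$species), species_list)
  if (length(missing)) {
    stop("species not in species_list: ", paste(missing, collapse = ", "))
  }
  fams <- names(partition$families)
  mat <- matrix(0L, nrow = length(fams), ncol = length(species_list),
                dimnames = list(fams, species_list))
  for (f in fams) mat[f, partition$species[[f]]] <- 1L
  mat
}

#' Read species-tagged mature miRNA catalogs
#'
#' FASTA headers follow the `id|species` convention; several files can be
#' combined. Sequences are normalized to RNA.
#'
#' @param paths FASTA file paths.
#' @return data.frame with columns `id`, `species`, `sequence`.
#' @export
read_mirna_catalog <- function(paths) {
  rows <- lapply(paths, function(p) {
    seqs <- read_fasta(p)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      stop("catalog header without 'id|species' tag: ",
           names(seqs)[bad[1]], " in ", p)
    }
    data.frame(id = vapply(parts, `[`, character(1), 1L),
               species = vapply(parts, `[`, character(1), 2L),
               sequence = as_rna(unname(seqs)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
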