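# Ground-truthed synthetic inputs for every pipeline stage: planted read
# mixtures (with adapters and contaminant classes), miRNA families evolved
# on a species tree under single-gain/multiple-loss, qPCR Ct tables with
# stage effects, and prediction tables with planted overlap and
# anti-correlation classes. Category counts are allocated by
# largest-remainder rounding so count assertions are exact; only ordering
# is randomized.

.READ_CATEGORIES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                      "exon", "intron", "other", "polyN", "adapter5",
                      "no_adapter3", "homopolymer", "low_quality")
.CLEAN_CATEGORIES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                       "exon", "intron", "other")

.default_read_mixture <- function() {
  setNames(c(0.35, 0.15, 0.08, 0.03, 0.03, 0.05, 0.08, 0.05, 0.06,
             0.02, 0.02, 0.04, 0.02, 0.02), .READ_CATEGORIES)
}

# qPCR panel mirroring a metamorphosis study: 9 miRNAs up at the
# metamorphic stage, 3 down, 2 flat. Values are fold changes relative to
# the reference stage (first column is 1 by definition).
.default_stage_effects <- function(stages = c("18", "21", "42")) {
  up <- c("miR-4040", "miR-4086", "miR-4055", "miR-4060", "miR-216a",
          "miR-216b", "miR-217", "miR-183", "miR-92c")
  down <- c("miR-4018a", "miR-4018b", "miR-4000f")
  flat <- c("miR-1497", "miR-1502")
  eff <- matrix(1, nrow = length(c(up, down, flat)), ncol = length(stages),
                dimnames = list(c(up, down, flat), stages))
  eff[up, length(stages)] <- 4
  eff[down, length(stages)] <- 0.25
  eff
}

#' Configuration for the synthetic data generator
#'
#' Defaults state the emulated world once: three developmental stages (18,
#' 21, 42 hpf) with triplicate qPCR, a 14-class read mixture over the
#' annotation and contaminant categories, mature miRNA lengths 21-24 nt
#' with a 0.8 first-base-U bias, and family histories with a single gain
#' and per-branch loss probability 0.1. A fixed seed makes every
#' generated artifact byte-identical.
#'
#' @param seed integer RNG seed.
#' @param tree rooted species `phylo` tree with named internal nodes.
#' @param n_families number of miRNA families to evolve.
#' @param loss_rate per-branch loss probability below the gain node.
#' @param read_mixture named fractions over the read categories (must sum
#'   to 1 within 1e-9).
#' @param n_reads total reads to generate.
#' @param n_mirnas size of the mature miRNA catalog backing miRNA reads.
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param first_base_u_bias fraction of catalog miRNAs starting with U.
#' @param stages stage labels, reference first.
#' @param n_replicates qPCR replicates per stage.
#' @param stage_effects fold-change matrix (miRNAs x stages) relative to
#'   the reference stage.
#' @param ct_noise_sd Ct noise standard deviation (Ct units).
#' @param pred_counts planted pair counts for the prediction tables:
#'   both-predictors, A-only anti-correlated, A-only positively
#'   correlated, B-only.
#' @param n_genes gene universe size for the prediction tables.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              tree = default_species_tree(),
                              n_families = 150L,
                              loss_rate = 0.1,
                              read_mixture = .default_read_mixture(),
                              n_reads = 10000L,
                              n_mirnas = 30L,
                              adapter_3p = "AGATCGGAAGAGCACACGTCT",
                              adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                              first_base_u_bias = 0.8,
                              stages = c("18", "21", "42"),
                              n_replicates = 3L,
                              stage_effects =
                                .default_stage_effects(stages),
                              ct_noise_sd = 0.25,
                              pred_counts = c(both = 15L, a_neg = 10L,
                                              a_pos = 10L, b_only = 10L),
                              n_genes = 60L) {
  cfg <- list(seed = as.integer(seed), tree = tree,
              n_families = as.integer(n_families), loss_rate = loss_rate,
              read_mixture = read_mixture, n_reads = as.integer(n_reads),
              n_mirnas = as.integer(n_mirnas),
              adapter_3p = as_dna(adapter_3p),
              adapter_5p = as_dna(adapter_5p),
              first_base_u_bias = first_base_u_bias,
              stages = as.character(stages),
              n_replicates = as.integer(n_replicates),
              stage_effects = stage_effects,
              ct_noise_sd = ct_noise_sd,
              pred_counts = pred_counts, n_genes = as.integer(n_genes))
  if (abs(sum(cfg$read_mixture) - 1) > 1e-9) {
    stop("read_mixture fractions must sum to 1")
  }
  if (any(cfg$read_mixture < 0)) stop("read_mixture fractions must be >= 0")
  bad <- setdiff(names(cfg$read_mixture), .READ_CATEGORIES)
  if (length(bad)) stop("unknown read categories: ",
                        paste(bad, collapse = ", "))
  stopifnot(cfg$loss_rate >= 0, cfg$loss_rate <= 1,
            cfg$first_base_u_bias >= 0, cfg$first_base_u_bias <= 1,
            cfg$ct_noise_sd >= 0, nzchar(cfg$adapter_3p))
  if (length(cfg$stages) < 2L) stop("need at least 2 stages")
  if (cfg$n_replicates < 2L) stop("need at least 2 replicates")
  class(cfg) <- "simulation_config"
  cfg
}

#' Evolve miRNA family histories on a species tree
#'
#' Each family receives a single gain at a node drawn uniformly from the
#' tree; every branch strictly below a still-present lineage then loses
#' the family with probability `loss_rate` (a loss silences the whole
#' subtree). Families that end present in zero species are discarded and
#' regenerated, so every row of the matrix has at least one 1.
#'
#' @param tree rooted `phylo` with >= 2 leaves and named internal nodes.
#' @param config a [simulation_config()].
#' @return list: `matrix` (families x species presence/absence), `truth`
#'   (per family: `gain` node id, `gain_name`, `losses` child node ids of
#'   loss branches).
#' @export
gen_family_history <- function(tree = NULL, config = simulation_config()) {
  if (is.null(tree)) tree <- config$tree
  validate_species_tree(tree)
  set.seed(config$seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- tree_children(tree)
  subt <- subtree_tips(tree)
  fam_names <- sprintf("fam%03d", seq_len(config$n_families))
  mat <- matrix(0L, nrow = config$n_families, ncol = ntip,
                dimnames = list(fam_names, tree$tip.label))
  truth <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    repeat {
      gain <- sample.int(nn, 1L)
      losses <- integer(0)
      present_tips <- integer(0)
      # preorder walk below the gain; a loss prunes its subtree
      stack <- gain
      while (length(stack)) {
        v <- stack[[1]]
        stack <- stack[-1]
        for (ch in kids[[v]]) {
          if (runif(1) < config$loss_rate) {
            losses <- c(losses, ch)  # maximal absent clade
          } else {
            stack <- c(stack, ch)
          }
        }
        if (v <= ntip) present_tips <- c(present_tips, v)
      }
      if (length(present_tips)) break
    }
    mat[i, present_tips] <- 1L
    truth[[i]] <- list(family = fam_names[i], gain = gain,
                       gain_name = node_name(tree, gain),
                       losses = sort(losses))
  }
  names(truth) <- fam_names
  list(matrix = mat, truth = truth)
}

# one ancestor per family, far from all previous ancestors at every
# allowed offset so cross-family pairs can never match
.new_ancestor <- function(existing, u_bias, min_cross_mismatch = 6L) {
  repeat {
    len <- sample(21:24, 1L)
    first <- if (runif(1) < u_bias) "U" else sample(c("A", "C", "G"), 1L)
    anc <- paste0(first, paste(sample(c("A", "C", "G", "U"), len - 1L,
                                      replace = TRUE), collapse = ""))
    ok <- TRUE
    for (e in existing) {
      for (o in -1:1) {
        ja1 <- max(1L, 1L + o)
        ja2 <- min(nchar(anc), nchar(e) + o)
        if (ja2 - ja1 + 1L < 15L) next
        mm <- hamming(substr(anc, ja1, ja2), substr(e, ja1 - o, ja2 - o))
        if (mm < min_cross_mismatch) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok) return(anc)
  }
}

#' Generate species-tagged mature miRNA sequences for evolved families
#'
#' Members of one family are copies of a family ancestor (21-24 nt, all
#' members equal length) carrying at most one substitution each, so every
#' within-family cross-species pair passes [pairwise_match()] (<= 2
#' mismatches at offset 0). Ancestors of different families are kept at
#' >= 6 mismatches at every allowed offset, so no cross-family pair can
#' pass even after per-member substitutions.
#'
#' @param mat presence/absence matrix from [gen_family_history()].
#' @param config a [simulation_config()].
#' @param p_substitution probability that a member carries one
#'   substitution relative to the ancestor.
#' @return data.frame: `id` (`<family>_<species>`), `species`, `family`,
#'   `sequence` (RNA).
#' @export
gen_family_sequences <- function(mat, config = simulation_config(),
                                 p_substitution = 0.4) {
  set.seed(config$seed + 1L)
  ancestors <- character(0)
  rows <- list()
  for (f in rownames(mat)) {
    anc <- .new_ancestor(ancestors, config$first_base_u_bias)
    ancestors <- c(ancestors, anc)
    for (sp in colnames(mat)[mat[f, ] == 1L]) {
      seq <- anc
      if (runif(1) < p_substitution) {
        pos <- sample.int(nchar(seq), 1L)
        cur <- substr(seq, pos, pos)
        substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "U"),
                                                cur), 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste(f, sp, sep = "_"), species = sp, family = f,
        sequence = seq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# category reference sequences used by gen_reads and handed to the
# annotation cascade
.gen_references <- function(config) {
  refs <- list()
  for (cat in c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "exon",
                "intron")) {
    refs[[cat]] <- setNames(random_seq(3L, 300L),
                            sprintf("%s_ref%d", cat, 1:3))
  }
  # mature catalog: first bases allocated exactly (largest remainder) so
  # the planted first-base-U frequency is the stated bias
  n <- config$n_mirnas
  n_u <- largest_remainder(c(U = config$first_base_u_bias,
                             other = 1 - config$first_base_u_bias), n)[["U"]]
  first <- c(rep("T", n_u), sample(c("A", "C", "G"), n - n_u,
                                   replace = TRUE))
  body <- random_seq(n, sample(21:24, n, replace = TRUE) - 1L)
  refs$known_miRNA <- setNames(paste0(first, body),
                               sprintf("csa-sim-miR-%03d", seq_len(n)))
  refs
}

# TRUE when read occurs (sense; both strands for exon/intron) in any of
# the given categories' references
.matches_categories <- function(read, refs, categories) {
  for (cat in categories) {
    subj <- paste(refs[[cat]], collapse = "\n")
    if (grepl(read, subj, fixed = TRUE)) return(TRUE)
    if (cat %in% c("exon", "intron") &&
        grepl(revcomp(read), subj, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Generate a planted small RNA read mixture with ground truth
#'
#' Per-category counts follow `config$read_mixture` exactly
#' (largest-remainder allocation; only read order is randomized). Clean
#' annotation-category reads are insert + full 3' adapter with high
#' quality; contaminant classes plant, respectively, N bases, a 5'
#' adapter prefix, a missing 3' adapter, a pure homopolymer insert, and
#' low quality. Inserts are re-drawn whenever they would collide with a
#' higher-priority annotation category or contain a spurious adapter
#' match, so downstream QC and classification counts equal the planted
#' counts exactly.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, writes `reads.fastq`
#'   and one `ref_<category>.fa` per annotation category.
#' @return list: `reads` (data.frame `id`, `seq`, `qual`, `category`),
#'   `references` (per-category named sequence vectors; the
#'   `known_miRNA` element is the mature catalog), `counts` (planted
#'   per-category counts).
#' @export
gen_reads <- function(config = simulation_config(), out_dir = NULL) {
  if (config$n_reads <= 0L) stop("n_reads must be positive")
  set.seed(config$seed + 2L)
  qc <- qc_params()
  refs <- .gen_references(config)
  counts <- largest_remainder(config$read_mixture, config$n_reads)
  priority <- intersect(.ANNOT_CATEGORIES, names(refs))
  higher <- function(cat) priority[seq_len(match(cat, priority) - 1L)]
  adapter <- config$adapter_3p
  good_q <- 35L
  # an insert is usable when the adapter locator fires nowhere inside the
  # bare insert (no adapter-prefix mimic, so re-filtering trimmed inserts
  # is idempotent) and, with the adapter appended, fires exactly at the
  # planted junction
  clean_read <- function(insert) {
    if (!is.na(locate_adapter(insert, adapter, qc$min_adapter_overlap,
                              qc$adapter_mismatches))) return(FALSE)
    pos <- locate_adapter(paste0(insert, adapter), adapter,
                          qc$min_adapter_overlap, qc$adapter_mismatches)
    !is.na(pos) && pos == nchar(insert) + 1L
  }
  draw_insert <- function(cat) {
    repeat {
      insert <- switch(cat,
        miRNA = as_dna(refs$known_miRNA[[sample.int(
          length(refs$known_miRNA), 1L)]]),
        other = random_seq(1L, sample(20:28, 1L)),
        {
          ref <- refs[[cat]][[sample.int(length(refs[[cat]]), 1L)]]
          len <- sample(18:28, 1L)
          start <- sample.int(nchar(ref) - len + 1L, 1L)
          s <- substr(ref, start, start + len - 1L)
          if (cat %in% c("exon", "intron") && runif(1) < 0.5) revcomp(s)
          else s
        })
      src <- if (cat == "miRNA") "known_miRNA" else cat
      if (cat == "other") {
        if (.matches_categories(insert, refs, priority)) next
      } else if (src %in% priority &&
                 .matches_categories(insert, refs, higher(src))) next
      if (!clean_read(insert)) next
      return(insert)
    }
  }
  reads <- list()
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0L) next
    for (i in seq_len(k)) {
      if (cat %in% .CLEAN_CATEGORIES) {
        insert <- draw_insert(cat)
        seq <- paste0(insert, adapter)
        qual <- phred_string(good_q, nchar(seq))
      } else if (cat == "polyN") {
        insert <- draw_insert("miRNA")
        pos <- sample.int(nchar(insert) - 3L, 1L) + 1L
        substr(insert, pos, pos + 1L) <- "NN"
        seq <- paste0(insert, adapter)
        qual <- phred_string(good_q, nchar(seq))
      } else if (cat == "adapter5") {
        insert <- draw_insert("miRNA")
        seq <- paste0(config$adapter_5p, insert, adapter)
        qual <- phred_string(good_q, nchar(seq))
      } else if (cat == "no_adapter3") {
        repeat {
          seq <- random_seq(1L, sample(30:40, 1L))
          if (is.na(locate_adapter(seq, adapter, qc$min_adapter_overlap,
                                   qc$adapter_mismatches))) break
        }
        qual <- phred_string(good_q, nchar(seq))
      } else if (cat == "homopolymer") {
        insert <- strrep(sample(c("A", "C", "G", "T"), 1L),
                         sample(20:24, 1L))
        seq <- paste0(insert, adapter)
        qual <- phred_string(good_q, nchar(seq))
      } else if (cat == "low_quality") {
        insert <- draw_insert("miRNA")
        seq <- paste0(insert, adapter)
        qual <- phred_string(8L, nchar(seq))
      }
      reads[[length(reads) + 1L]] <- list(seq = seq, qual = qual,
                                          category = cat)
    }
  }
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  df <- data.frame(
    id = sprintf("read%05d", seq_along(reads)),
    seq = vapply(reads, `[[`, character(1), "seq"),
    qual = vapply(reads, `[[`, character(1), "qual"),
    category = vapply(reads, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(df, file.path(out_dir, "reads.fastq"))
    for (cat in names(refs)) {
      write_fasta(refs[[cat]],
                  file.path(out_dir, paste0("ref_", cat, ".fa")))
    }
  }
  list(reads = df, references = refs, counts = counts)
}

#' Generate a qPCR Ct table with planted stage effects
#'
#' Each miRNA's Ct at a stage is its baseline minus log2 of the planted
#' fold change, plus Gaussian noise; the U6 normalizer has zero stage
#' effect by definition. With zero noise the 2^-ddCt estimate equals the
#' planted fold change exactly.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; writes `ct.csv` and
#'   `stage_expression.tsv` (per-miRNA per-stage planted expression).
#' @return list: `ct` (data.frame `mirna`, `stage`, `replicate`, `ct`,
#'   U6 rows included), `truth` (the fold-change matrix),
#'   `stage_matrix` (planted per-stage expression levels).
#' @export
gen_expression <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed + 3L)
  eff <- config$stage_effects
  stopifnot(!is.null(rownames(eff)),
            identical(colnames(eff), config$stages))
  mirnas <- rownames(eff)
  baseline <- setNames(runif(length(mirnas), 22, 28), mirnas)
  u6_ct <- 15
  rows <- list()
  for (s in seq_along(config$stages)) {
    for (r in seq_len(config$n_replicates)) {
      for (m in mirnas) {
        ctv <- baseline[[m]] - log2(eff[m, s]) +
          rnorm(1, sd = config$ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, stage = config$stages[s], replicate = r, ct = ctv,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = "U6", stage = config$stages[s], replicate = r,
        ct = u6_ct + rnorm(1, sd = config$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  stage_matrix <- eff * 100  # planted expression level, arbitrary units
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ct, file.path(out_dir, "ct.csv"), row.names = FALSE)
    write.table(data.frame(mirna = rownames(stage_matrix), stage_matrix,
                           check.names = FALSE),
                file.path(out_dir, "stage_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(ct = ct, truth = eff, stage_matrix = stage_matrix)
}

#' Generate two prediction tables with planted integration classes
#'
#' Plants four pair classes over a synthetic gene universe:
#' both-predictor pairs, A-only pairs with negatively correlated gene
#' profiles, A-only pairs with positively correlated profiles, and B-only
#' pairs. The integration rule must keep exactly the first two classes.
#' Genes are distinct across pairs so class labels are unambiguous.
#'
#' @param config a [simulation_config()]; miRNAs with non-constant
#'   planted profiles are drawn from `stage_effects`.
#' @param out_dir optional directory; writes `pred_a.tsv`, `pred_b.tsv`,
#'   `mirna_expression.tsv`, `gene_expression.tsv`, `gene_sets.gmt`.
#' @return list: `table_a`, `table_b`, `mirna_profiles`,
#'   `gene_profiles`, `truth` (data.frame `mirna`, `gene`, `class`,
#'   `kept`), `gene_sets`, `universe`.
#' @export
gen_prediction_tables <- function(config = simulation_config(),
                                  out_dir = NULL) {
  set.seed(config$seed + 4L)
  if (config$n_genes < 10L) stop("gene universe must have >= 10 genes")
  counts <- config$pred_counts
  stopifnot(all(c("both", "a_neg", "a_pos", "b_only") %in% names(counts)))
  n_pairs <- sum(counts)
  if (n_pairs > config$n_genes) {
    stop("need at least as many genes as planted pairs")
  }
  genes <- sprintf("g%03d", seq_len(config$n_genes))
  eff <- config$stage_effects
  de <- rownames(eff)[apply(eff, 1L, sd) > 0]
  if (length(de) == 0L) stop("stage_effects has no non-constant miRNA")
  mirna_profiles <- eff[de, , drop = FALSE] * 100
  classes <- rep(names(counts), counts)
  pair_genes <- sample(genes, n_pairs)
  pair_mirnas <- sample(de, n_pairs, replace = TRUE)
  gene_profiles <- matrix(NA_real_, nrow = config$n_genes,
                          ncol = ncol(eff),
                          dimnames = list(genes, colnames(eff)))
  for (i in seq_len(n_pairs)) {
    m <- mirna_profiles[pair_mirnas[i], ]
    prof <- switch(classes[i],
      a_neg = max(m) + min(m) - m,              # mirror: exactly r = -1
      a_pos = m,                                # aligned: exactly r = +1
      runif(ncol(eff), 50, 150))
    prof <- prof + rnorm(length(prof), sd = 0.01 * max(1, sd(prof)))
    # noise is tiny but re-check the planted sign anyway
    if (classes[i] == "a_neg") while (cor(m, prof) >= 0) {
      prof <- max(m) + min(m) - m + rnorm(length(m), sd = 0.01)
    }
    if (classes[i] == "a_pos") while (cor(m, prof) <= 0) {
      prof <- m + rnorm(length(m), sd = 0.01)
    }
    gene_profiles[pair_genes[i], ] <- prof
  }
  unused <- is.na(gene_profiles[, 1])
  gene_profiles[unused, ] <- matrix(
    runif(sum(unused) * ncol(eff), 50, 150), ncol = ncol(eff))
  in_a <- classes %in% c("both", "a_neg", "a_pos")
  in_b <- classes %in% c("both", "b_only")
  table_a <- data.frame(mirna = pair_mirnas[in_a],
                        gene = pair_genes[in_a],
                        score = round(runif(sum(in_a), 140, 180), 1),
                        energy = round(-runif(sum(in_a), 8, 30), 2),
                        stringsAsFactors = FALSE)
  table_b <- data.frame(mirna = pair_mirnas[in_b],
                        gene = pair_genes[in_b],
                        score = round(runif(sum(in_b), 0.2, 0.9), 3),
                        stringsAsFactors = FALSE)
  truth <- data.frame(mirna = pair_mirnas, gene = pair_genes,
                      class = classes,
                      kept = classes %in% c("both", "a_neg"),
                      stringsAsFactors = FALSE)
  kept_genes <- truth$gene[truth$kept]
  # one set enriched in kept targets plus random background sets
  gene_sets <- list(planted_pathway = c(
    sample(kept_genes, min(8L, length(kept_genes))),
    sample(setdiff(genes, kept_genes), 2L)))
  for (i in 2:5) {
    gene_sets[[sprintf("random_set_%d", i)]] <- sample(genes, 10L)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(table_a, file.path(out_dir, "pred_a.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(table_b, file.path(out_dir, "pred_b.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(mirna = rownames(mirna_profiles),
                           mirna_profiles, check.names = FALSE),
                file.path(out_dir, "mirna_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = rownames(gene_profiles), gene_profiles,
                           check.names = FALSE),
                file.path(out_dir, "gene_expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  }
  list(table_a = table_a, table_b = table_b,
       mirna_profiles = mirna_profiles, gene_profiles = gene_profiles,
       truth = truth, gene_sets = gene_sets, universe = genes)
}
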