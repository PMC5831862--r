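# Generator contracts: exact planted counts, determinism, replayable
# family histories, and self-consistency with the analysis modules.

test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  bad_mix <- mirmeta:::.default_read_mixture()
  bad_mix[1] <- bad_mix[1] + 0.05
  expect_error(simulation_config(read_mixture = bad_mix), "sum to 1")
  expect_error(simulation_config(loss_rate = 1.5))
  expect_error(simulation_config(stages = "18"), "2 stages")
  expect_error(simulation_config(n_replicates = 1), "2 replicates")
})

test_that("family histories are single-gain and replay to the matrix", {
  cfg <- simulation_config(seed = 1, n_families = 200, loss_rate = 0.1)
  tree <- cfg$tree
  out <- gen_family_history(tree, cfg)
  expect_equal(dim(out$matrix),
               c(200L, length(tree$tip.label)))
  expect_true(all(rowSums(out$matrix) >= 1))
  # replay oracle: recompute each presence row from the recorded events
  par <- mirmeta:::tree_parents(tree)
  subt <- mirmeta:::subtree_tips(tree)
  for (f in rownames(out$matrix)) {
    tr <- out$truth[[f]]
    expect_length(tr$gain, 1)  # exactly one gain (Dollo-compatible)
    replay <- Filter(function(tip) {
      v <- tip
      while (!is.na(v) && v != tr$gain) {
        if (v %in% tr$losses) return(FALSE)
        v <- par[v]
      }
      TRUE
    }, subt[[tr$gain]])
    expect_identical(which(out$matrix[f, ] == 1L), sort(as.integer(replay)),
                     ignore_attr = TRUE)
    # losses lie strictly below the gain node
    expect_true(all(tr$losses %in% mirmeta:::descendants(tree, tr$gain)))
  }
})

test_that("loss_rate 0 with gains at the root gives all-ones rows", {
  cfg <- simulation_config(seed = 3, n_families = 20, loss_rate = 0)
  out <- gen_family_history(cfg$tree, cfg)
  root_fams <- names(Filter(function(t) t$gain ==
                              mirmeta:::tree_root(cfg$tree), out$truth))
  expect_gt(length(root_fams), 0)
  for (f in root_fams) expect_true(all(out$matrix[f, ] == 1L))
})

test_that("degenerate trees are rejected", {
  one_leaf <- structure(list(edge = matrix(c(2L, 1L), 1), Nnode = 1L,
                             tip.label = "A"), class = "phylo")
  expect_error(gen_family_history(one_leaf, simulation_config()),
               "2 leaves")
})

test_that("generated family sequences respect the planted partition", {
  cfg <- simulation_config(seed = 11, n_families = 20)
  hist <- gen_family_history(cfg$tree, cfg)
  seqs <- gen_family_sequences(hist$matrix, cfg)
  expect_true(all(nchar(seqs$sequence) %in% 21:24))
  # within-family pairs match; cross-family pairs never do
  by_fam <- split(seqs$sequence, seqs$family)
  for (f in names(by_fam)) {
    ss <- by_fam[[f]]
    if (length(ss) < 2) next
    for (i in seq_len(length(ss) - 1)) {
      expect_true(pairwise_match(ss[i], ss[i + 1])$match)
    }
  }
  fams <- names(by_fam)
  for (i in seq_len(min(8, length(fams) - 1))) {
    a <- by_fam[[fams[i]]][1]
    for (j in seq(i + 1, min(i + 4, length(fams)))) {
      expect_false(pairwise_match(a, by_fam[[fams[j]]][1])$match)
    }
  }
})

test_that("read mixtures hit their planted counts exactly", {
  cfg <- simulation_config(seed = 5, n_reads = 1000)
  out <- gen_reads(cfg)
  expect_identical(sum(out$counts), 1000L)  # conservation
  expect_identical(as.integer(table(out$reads$category)[names(out$counts)]),
                   unname(out$counts))
  # deterministic allocation: 5% polyN of 1000 -> exactly 50 reads with Ns
  expect_identical(
    out$counts[["polyN"]],
    largest_remainder(cfg$read_mixture, 1000L)[["polyN"]])
  has_n <- grepl("N", out$reads$seq, fixed = TRUE)
  expect_identical(sum(has_n), out$counts[["polyN"]])
})

test_that("a pure clean-miRNA mixture yields only adapter-bearing reads", {
  mix <- setNames(rep(0, length(mirmeta:::.READ_CATEGORIES)),
                  mirmeta:::.READ_CATEGORIES)
  mix["miRNA"] <- 1
  cfg <- simulation_config(seed = 2, n_reads = 100, read_mixture = mix)
  out <- gen_reads(cfg)
  expect_identical(nrow(out$reads), 100L)
  expect_false(any(grepl("N", out$reads$seq, fixed = TRUE)))
  qc <- filter_reads(out$reads, cfg$adapter_3p, cfg$adapter_5p)
  expect_identical(qc$report$clean_reads, 100L)
})

test_that("gen_reads rejects non-positive read counts", {
  expect_error(gen_reads(simulation_config(n_reads = 0)), "positive")
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 42, n_reads = 300, n_families = 15)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  gen_reads(cfg, out_dir = d1)
  gen_expression(cfg, out_dir = d1)
  gen_prediction_tables(cfg, out_dir = d1)
  gen_reads(cfg, out_dir = d2)
  gen_expression(cfg, out_dir = d2)
  gen_prediction_tables(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("planted expression effects are exact at zero noise", {
  eff <- matrix(c(1, 1, 2,
                  1, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("mirX", "mirFlat"), c("18", "21", "42")))
  cfg <- simulation_config(seed = 9, stage_effects = eff, ct_noise_sd = 0)
  out <- gen_expression(cfg)
  expect_true("U6" %in% out$ct$mirna)
  res <- ddct(out$ct, reference_stage = "18")
  s <- res$summary
  expect_equal(s$fold_change[s$mirna == "mirX" & s$stage == "42"], 2.0)
  expect_equal(s$fold_change[s$mirna == "mirFlat"], rep(1.0, 3))
})

test_that("direction is recovered for all planted |log2FC| >= 1 effects", {
  cfg <- simulation_config(seed = 3, ct_noise_sd = 0.1)
  out <- gen_expression(cfg)
  res <- ddct(out$ct, reference_stage = "18")
  tests <- stage_test(res, final_stage = "42", alpha = 0.01)
  truth_dir <- ifelse(cfg$stage_effects[, "42"] > 1, "up",
                      ifelse(cfg$stage_effects[, "42"] < 1, "down",
                             "unchanged"))
  strong <- abs(log2(cfg$stage_effects[, "42"])) >= 1
  got <- setNames(tests$direction, tests$mirna)
  expect_identical(got[names(truth_dir)[strong]],
                   truth_dir[strong])
})

test_that("prediction tables plant the four integration classes", {
  cfg <- simulation_config(seed = 11)
  out <- gen_prediction_tables(cfg)
  expect_identical(as.integer(table(out$truth$class)[c(
    "both", "a_neg", "a_pos", "b_only")]),
    unname(as.integer(cfg$pred_counts[c("both", "a_neg", "a_pos",
                                        "b_only")])))
  ka <- paste(out$table_a$mirna, out$table_a$gene)
  kb <- paste(out$table_b$mirna, out$table_b$gene)
  kt <- paste(out$truth$mirna, out$truth$gene)
  expect_setequal(ka, kt[out$truth$class %in% c("both", "a_neg", "a_pos")])
  expect_setequal(kb, kt[out$truth$class %in% c("both", "b_only")])
  # planted correlation signs hold
  for (i in which(out$truth$class == "a_neg")) {
    r <- cor(out$mirna_profiles[out$truth$mirna[i], ],
             out$gene_profiles[out$truth$gene[i], ])
    expect_lt(r, 0)
  }
  expect_error(gen_prediction_tables(simulation_config(n_genes = 5)),
               ">= 10")
})
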