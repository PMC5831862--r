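# Seed sites, the integration rule, network export, enrichment.

test_that("seed_sites finds planted reverse-complement heptamers", {
  mir <- "UACGUACGAUCGAUCGAUCGAU"   # seed (2-8) = ACGUACG
  site <- as_dna(revcomp("ACGUACG"))  # CGTACGT
  utr <- paste0("AAAA", site, "GGGGGGGG", site, "TTTT")
  hits <- seed_sites(mir, utr)
  expect_identical(hits$start, c(4L, 19L))  # ascending, 0-based
  expect_identical(hits$end, hits$start + 7L)
  expect_identical(unique(hits$site), site)
  # no-complement UTR gives an empty frame; brute-force oracle agrees
  set.seed(77)
  for (i in 1:50) {
    utr2 <- mirmeta:::random_seq(1, 300)
    got <- seed_sites(mir, utr2)$start
    width <- nchar(site)
    oracle <- which(vapply(seq_len(nchar(utr2) - width + 1), function(p)
      substr(utr2, p, p + width - 1) == site, logical(1))) - 1L
    expect_identical(got, as.integer(oracle))
  }
  expect_error(seed_sites("UACGXACG", utr), "non-nucleotide")
  expect_error(seed_sites(mir, "ACGT"), "shorter than the seed")
})

test_that("the integration rule keeps overlap and anti-correlated pairs", {
  profiles_m <- matrix(c(1, 2, 4), 1, dimnames = list("m1", NULL))
  profiles_g <- matrix(c(4, 2, 1,   # anti-correlated with m1
                         1, 2, 4,   # positively correlated
                         2, 2, 2),  # constant: r undefined
                       3, byrow = TRUE,
                       dimnames = list(c("gneg", "gpos", "gflat"), NULL))
  ta <- data.frame(mirna = "m1", gene = c("gboth", "gneg", "gpos"),
                   energy = c(-20, -10, -5))
  tb <- data.frame(mirna = "m1", gene = c("gboth", "gonly"))
  edges <- integrate_targets(ta, tb, profiles_m, profiles_g)
  expect_identical(edges$gene, c("gboth", "gneg"))
  expect_identical(edges$evidence, c("overlap", "anti_correlation"))
  expect_identical(edges$energy, c(-20, -10))  # carried from table A
  expect_lt(edges$correlation[2], 0)
  # a pair in both tables with r < 0 records both clauses
  ta2 <- data.frame(mirna = "m1", gene = "gneg")
  tb2 <- data.frame(mirna = "m1", gene = "gneg")
  expect_identical(
    integrate_targets(ta2, tb2, profiles_m, profiles_g)$evidence, "both")
  # positive energies and duplicate rows are rejected
  expect_error(integrate_targets(
    data.frame(mirna = "m", gene = "g", energy = 3), tb), "<= 0")
  expect_error(integrate_targets(
    data.frame(mirna = c("m", "m"), gene = c("g", "g")), tb),
    "duplicate")
})

test_that("short profiles disable the correlation clause with a warning", {
  pm <- matrix(c(1, 4), 1, dimnames = list("m1", NULL))
  pg <- matrix(c(4, 1), 1, dimnames = list("gneg", NULL))
  ta <- data.frame(mirna = "m1", gene = c("gboth", "gneg"))
  tb <- data.frame(mirna = "m1", gene = "gboth")
  expect_warning(edges <- integrate_targets(ta, tb, pm, pg),
                 "disabled")
  expect_identical(edges$gene, "gboth")
})

test_that("integration properties hold on random tables", {
  set.seed(99)
  stages <- 3
  for (rep in 1:10) {
    mirnas <- sprintf("m%d", 1:4)
    genes <- sprintf("g%d", 1:12)
    pm <- matrix(runif(4 * stages), 4, dimnames = list(mirnas, NULL))
    pg <- matrix(runif(12 * stages), 12, dimnames = list(genes, NULL))
    pairs <- expand.grid(mirna = mirnas, gene = genes,
                         stringsAsFactors = FALSE)
    ta <- pairs[sample(nrow(pairs), 20), ]
    tb <- pairs[sample(nrow(pairs), 20), ]
    e0 <- integrate_targets(ta, tb, pm, pg, max_r = 0)
    e5 <- integrate_targets(ta, tb, pm, pg, max_r = 0.5)
    k <- function(e) paste(e$mirna, e$gene)
    # monotonicity: relaxing max_r never removes an edge
    expect_true(all(k(e0) %in% k(e5)))
    # A intersect B is always kept
    inter <- intersect(paste(ta$mirna, ta$gene), paste(tb$mirna, tb$gene))
    expect_true(all(inter %in% k(e0)))
    # output sorted by (mirna, gene)
    expect_identical(order(e0$mirna, e0$gene), seq_len(nrow(e0)))
  }
})

test_that("integration recovers the planted four-class truth", {
  out <- gen_prediction_tables(simulation_config(seed = 31))
  edges <- integrate_targets(out$table_a, out$table_b,
                             out$mirna_profiles, out$gene_profiles)
  expect_setequal(paste(edges$mirna, edges$gene),
                  paste(out$truth$mirna, out$truth$gene)[out$truth$kept])
  cls <- setNames(out$truth$class, paste(out$truth$mirna, out$truth$gene))
  got_cls <- cls[paste(edges$mirna, edges$gene)]
  expect_true(all(edges$evidence[got_cls == "a_neg"] ==
                    "anti_correlation"))
  expect_true(all(edges$evidence[got_cls == "both"] %in%
                    c("overlap", "both")))
})

test_that("network export is deterministic and round-trips", {
  p <- tempfile(fileext = ".tsv")
  export_network(data.frame(mirna = character(0), gene = character(0),
                            evidence = character(0)), p)
  expect_identical(length(readLines(p)), 1L)  # header only
  edges <- data.frame(mirna = c("m2", "m1", "m1"),
                      gene = c("g1", "g2", "g1"),
                      evidence = "overlap", correlation = NA_real_,
                      energy = c(-1, -2, -3))
  export_network(edges, p)
  back <- read.delim(p)
  expect_identical(back$mirna, c("m1", "m1", "m2"))  # sorted
  expect_identical(back$gene, c("g1", "g2", "g1"))
  expect_equal(back$energy, c(-3, -2, -1))
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- sprintf("g%03d", 1:100)
  genes <- universe[1:5]
  sets <- list(hit = universe[1:10], miss = universe[90:99],
               all = universe)
  res <- enrich(genes, sets, universe)
  p_closed <- choose(10, 5) / choose(100, 5)  # all 5 inside the 10-set
  expect_equal(res$p[res$set == "hit"], p_closed, tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1)
  expect_equal(res$p[res$set == "miss"], 1)  # disjoint, one-sided
  expect_identical(res$overlap[res$set == "miss"], 0L)
  expect_identical(res$q, p.adjust(res$p, "BH"))
  expect_error(enrich(genes, sets, character(0)), "empty universe")
  expect_error(enrich(c(genes, "zzz"), sets, universe), "outside")
})

test_that("hypergeometric p agrees with Monte-Carlo resampling", {
  set.seed(123)
  universe <- sprintf("g%02d", 1:40)
  set <- universe[1:12]
  genes <- universe[c(1:4, 20:23)]  # 8 draws, overlap 4
  p <- enrich(genes, list(s = set), universe)$p
  draws <- replicate(100000,
    sum(sample(universe, length(genes)) %in% set) >=
      sum(genes %in% set))
  mc <- mean(draws)
  se <- sqrt(mc * (1 - mc) / length(draws))
  expect_lt(abs(p - mc), 3 * se)
})
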