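# Comparative Ct quantification and stage testing.

make_ct <- function(dct_by_stage, u6 = 15, reps = 3, mirna = "mirX",
                    noise = 0) {
  rows <- list()
  for (s in names(dct_by_stage)) {
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        mirna = c(mirna, "U6"), stage = s, replicate = r,
        ct = c(u6 + dct_by_stage[[s]] + rnorm(1, sd = noise), u6))
    }
  }
  do.call(rbind, rows)
}

test_that("2^-ddCt follows the closed form", {
  # ddCt 0 -> 1; ddCt -1 -> 2
  ct <- make_ct(c(`18` = 5, `21` = 5, `42` = 4))
  res <- ddct(ct, reference_stage = "18")
  s <- res$summary
  expect_equal(s$fold_change[s$stage == "18"], 1.0)
  expect_equal(s$fold_change[s$stage == "21"], 1.0)
  expect_equal(s$fold_change[s$stage == "42"], 2.0)
  expect_equal(s$ddct[s$stage == "42"], -1.0)
  expect_true(all(s$sd_rel >= 0))
})

test_that("reference-stage fold change is 1 on replicate means, always", {
  set.seed(91)
  for (i in 1:20) {
    ct <- make_ct(c(`18` = runif(1, 2, 8), `21` = runif(1, 2, 8),
                    `42` = runif(1, 2, 8)), noise = 0.5)
    res <- ddct(ct, reference_stage = "18")
    s <- res$summary
    expect_equal(s$fold_change[s$stage == "18"], 1.0, tolerance = 1e-12)
  }
})

test_that("relative expression is invariant to a shared Ct shift", {
  set.seed(92)
  ct <- make_ct(c(`18` = 5, `21` = 6, `42` = 3), noise = 0.3)
  res1 <- ddct(ct, reference_stage = "18")
  ct2 <- ct
  shift <- ct2$stage == "21" & ct2$replicate == 2  # both target and U6
  ct2$ct[shift] <- ct2$ct[shift] + 3.7
  res2 <- ddct(ct2, reference_stage = "18")
  expect_equal(res1$summary$fold_change, res2$summary$fold_change)
})

test_that("missing reference rows are rejected", {
  ct <- make_ct(c(`18` = 5, `42` = 4))
  expect_error(ddct(ct[ct$mirna != "U6", ], reference_stage = "18"),
               "reference assay")
  expect_error(ddct(ct, reference_stage = "21"), "reference stage")
  drop_one <- ct[!(ct$mirna == "U6" & ct$stage == "42" &
                     ct$replicate == 2), ]
  expect_error(ddct(drop_one, reference_stage = "18"), "missing U6")
  bad <- ct
  bad$ct[1] <- -1
  expect_error(ddct(bad, reference_stage = "18"), "finite and positive")
})

test_that("the t statistic matches the hand-computed Student formula", {
  x <- c(4.81, 5.20, 4.93)
  y <- c(6.02, 5.88, 6.31)
  ct <- rbind(
    data.frame(mirna = "m", stage = "42", replicate = 1:3, ct = 15 + x),
    data.frame(mirna = "m", stage = "18", replicate = 1:3, ct = 15 + y),
    data.frame(mirna = "U6", stage = "42", replicate = 1:3, ct = 15),
    data.frame(mirna = "U6", stage = "18", replicate = 1:3, ct = 15))
  res <- ddct(ct, reference_stage = "18")
  p_pkg <- stage_test(res, final_stage = "42")$p_18
  sp <- sqrt(((3 - 1) * var(x) + (3 - 1) * var(y)) / 4)
  t_stat <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_stat), df = 4)
  expect_equal(p_pkg, p_hand, tolerance = 1e-12)
})

test_that("degenerate groups follow the p-value conventions", {
  ct <- make_ct(c(`18` = 5, `21` = 5, `42` = 5))
  res <- ddct(ct, reference_stage = "18")
  out <- stage_test(res, final_stage = "42")
  expect_equal(out$p_max, 1)  # identical groups
  expect_identical(out$direction, "unchanged")
  ct2 <- make_ct(c(`18` = 5, `21` = 5, `42` = 3))
  out2 <- stage_test(ddct(ct2, reference_stage = "18"),
                     final_stage = "42")
  expect_equal(out2$p_max, 0)  # zero variance, different means
  expect_identical(out2$direction, "up")
})

test_that("a strong planted effect is flagged with the right direction", {
  set.seed(17)
  # log2FC = 3 at 42 hpf, sd = 0.1, n = 3: power ~ 1 at alpha 0.01
  ct <- make_ct(c(`18` = 6, `21` = 6, `42` = 3), noise = 0.1)
  out <- stage_test(ddct(ct, reference_stage = "18"), final_stage = "42",
                    alpha = 0.01)
  expect_true(out$significant)
  expect_identical(out$direction, "up")
  # significance requires BOTH earlier stages to differ
  ct2 <- make_ct(c(`18` = 6, `21` = 3, `42` = 3), noise = 0.1)
  out2 <- stage_test(ddct(ct2, reference_stage = "18"),
                     final_stage = "42")
  expect_false(out2$significant)
})

test_that("heatmap clustering orders rows deterministically", {
  eff <- matrix(c(1, 1, 4,
                  1, 1, 4,
                  4, 2, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("mirA", "mirB", "mirC"),
                                c("18", "21", "42")))
  cfg <- simulation_config(seed = 4, stage_effects = eff, ct_noise_sd = 0)
  res <- ddct(gen_expression(cfg)$ct, reference_stage = "18")
  hm <- cluster_heatmap_matrix(res)
  # the two identical rows merge first at distance 0
  expect_equal(hm$hclust$height[1], 0)
  first_pair <- sort(hm$hclust$labels[-hm$hclust$merge[1, ]])
  expect_identical(first_pair, c("mirA", "mirB"))
  # the anti-correlated outlier joins the merged pair last
  expect_true(1 %in% hm$hclust$merge[2, ])
  expect_gt(hm$hclust$height[2], 1)  # 1 - r with r < 0
  # permuting the input leaves the dendrogram topology unchanged
  ct2 <- gen_expression(cfg)$ct
  ct2 <- ct2[rev(seq_len(nrow(ct2))), ]
  hm2 <- cluster_heatmap_matrix(ddct(ct2, reference_stage = "18"))
  expect_equal(hm$hclust$height, hm2$hclust$height)
  expect_identical(hm$order, hm2$order)
  expect_error(cluster_heatmap_matrix(
    ddct(make_ct(c(`18` = 5, `42` = 4)), reference_stage = "18")),
    "two miRNAs")
})

test_that("stage profiles come back in fixed order with flags", {
  eff <- matrix(c(4, 2, 1), nrow = 1,
                dimnames = list("mirDec", c("18", "21", "42")))
  cfg <- simulation_config(seed = 6, stage_effects = eff, ct_noise_sd = 0)
  res <- ddct(gen_expression(cfg)$ct, reference_stage = "18")
  v <- stage_profile_vector(res, "mirDec")
  expect_identical(names(v), c("18", "21", "42"))
  expect_true(all(diff(v) < 0))  # planted decreasing profile
  expect_false(attr(v, "constant"))
  flat <- matrix(1, nrow = 1, ncol = 3,
                 dimnames = list("mirFlat", c("18", "21", "42")))
  cfgf <- simulation_config(seed = 6, stage_effects = flat,
                            ct_noise_sd = 0)
  vf <- stage_profile_vector(ddct(gen_expression(cfgf)$ct,
                                  reference_stage = "18"), "mirFlat")
  expect_true(attr(vf, "constant"))
  expect_error(stage_profile_vector(res, "mirDec", stages = "18"),
               "two stages")
  expect_error(stage_profile_vector(res, "nope"), "unknown miRNA")
})
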