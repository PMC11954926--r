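test_that("average precision matches hand evaluation and the sweep oracle", {
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(average_precision(c(4, 3, 2, 1), c(0, 1, 0, 1)), 0.5)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    scores <- round(runif(n), 2)  # many ties
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1L
    expect_equal(average_precision(scores, labels),
                 oracle_ap(scores, labels)$ap, tolerance = 1e-12)
  }
  expect_error(average_precision(1:4, c(0, 0, 0, 0)), "positive")
})

test_that("random scores give AP near prevalence at large n", {
  set.seed(9)
  n <- 20000; prev <- 0.05
  labels <- rbinom(n, 1, prev)
  ap <- average_precision(runif(n), labels)
  expect_equal(ap, mean(labels), tolerance = 0.25)
})

test_that("PR curve has non-decreasing recall and matches the oracle pointwise", {
  set.seed(4)
  scores <- sample(1:20, 60, replace = TRUE)
  labels <- rbinom(60, 1, 0.4)
  pr <- pr_curve(scores, labels)
  expect_true(all(diff(pr$recall) >= 0))
  orc <- oracle_ap(scores, labels)$points
  expect_equal(pr$precision, unname(orc[, "precision"]))
  expect_equal(pr$recall, unname(orc[, "recall"]))
  # single positive ranked first
  pr1 <- pr_curve(10:1, c(1, rep(0, 9)))
  expect_equal(pr1$precision[1], 1)
  expect_equal(pr1$recall[1], 1)
  # binary predictor collapses to a single informative point + the tail
  prb <- pr_curve(c(1, 1, 0, 0, 0), c(1, 0, 0, 1, 0))
  expect_equal(nrow(prb), 2L)
  pc <- precision_at_cutoff(c(1, 1, 0, 0, 0), c(1, 0, 0, 1, 0), cutoff = 1)
  expect_equal(pc$precision, 0.5)
  expect_equal(pc$recall, 0.5)
})

test_that("per-tissue-type AP pools tissues and is invariant to duplicated tissues", {
  map <- data.table(tissue = c("a", "b", "c"),
                    tissue_type = c("T1", "T1", "T2"))
  set.seed(6)
  one <- data.table(score = runif(50), label = rbinom(50, 1, 0.3), tissue = "c")
  res <- per_tissue_type_auprc(one, map)
  expect_equal(res[tissue_type == "T2", auprc],
               average_precision(one$score, one$label))
  # identical data in two tissues of one type pools to the same AP
  two <- rbind(copy(one)[, tissue := "a"], copy(one)[, tissue := "b"])
  res2 <- per_tissue_type_auprc(two, map)
  expect_equal(res2[tissue_type == "T1", auprc],
               average_precision(one$score, one$label))
  expect_error(per_tissue_type_auprc(copy(one)[, tissue := "zz"], map),
               "missing")
})

test_that("the shipped tissue-type map covers 49 tissues in 27 types", {
  map <- gtex_tissue_types()
  expect_equal(nrow(map), 49L)
  expect_equal(uniqueN(map$tissue_type), 27L)
  expect_true(all(cat_tissue_exclusions("fibroblasts") %in% map$tissue))
  expect_true(all(cat_tissue_exclusions("whole_blood") %in% map$tissue))
})

test_that("paired model comparison uses the exact signed-rank distribution", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(paired_model_comparison(x, x)$p_value, 1)
  # strict dominance over 10 types: minimal exact two-sided p = 2/2^10
  set.seed(8)
  a <- runif(10, 0.5, 1); b <- a - runif(10, 0.01, 0.1)
  expect_equal(paired_model_comparison(a, b)$p_value, 2 / 1024)
  # n = 6 toy against exhaustive sign-flip enumeration
  for (i in 1:10) {
    a6 <- runif(6); b6 <- runif(6)
    d <- a6 - b6
    if (any(d == 0) || any(duplicated(abs(d)))) next
    expect_equal(paired_model_comparison(a6, b6)$p_value,
                 oracle_signed_rank_p(d))
  }
})

test_that("consequence classes are ordered by Fisher significance and assigned", {
  # single class present
  single <- assign_consequence_class(
    list("synonymous_variant", "synonymous_variant", character(0)),
    c(1, 0, 0))
  expect_equal(single$assigned, c("Synonymous", "Synonymous", NA))

  # planted: NMD strongly outlier-associated, synonymous not
  set.seed(10)
  n <- 120
  nmd <- rbinom(n, 1, 0.2)
  out <- ifelse(nmd == 1, rbinom(n, 1, 0.8), rbinom(n, 1, 0.05))
  sets <- lapply(seq_len(n), function(i) {
    s <- "synonymous_variant"
    if (nmd[i]) s <- c(s, "stop_gained")
    s
  })
  res <- assign_consequence_class(sets, out)
  expect_equal(res$ordering$class[1], "NMD-like")
  # rows carrying both classes get the more significant one
  expect_true(all(res$assigned[nmd == 1] == "NMD-like"))
  expect_true(all(res$assigned[nmd == 0] == "Synonymous"))
  # the Fisher p values match hypergeometric enumeration
  a <- sum(nmd == 1 & out == 1); b <- sum(nmd == 1 & out == 0)
  cc <- sum(nmd == 0 & out == 1); d <- sum(nmd == 0 & out == 0)
  expect_equal(res$ordering[class == "NMD-like", p],
               oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
  # ordering invariant to row permutation
  perm <- sample(n)
  res_p <- assign_consequence_class(sets[perm], out[perm])
  expect_equal(res_p$ordering$class, res$ordering$class)
})

test_that("enrichment odds ratios match the cross-product and flag zero cells", {
  # table (10, 90, 5, 95): OR = (10*95)/(90*5)
  hi <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  cls <- c(rep("rare", 100), rep("common", 200 - 100))
  res <- enrichment_odds_ratio(hi, factor(cls, levels = c("common", "rare")))
  expect_equal(res$or, (10 * 95) / (90 * 5), tolerance = 1e-6)
  expect_false(res$corrected)
  expect_true(res$ci_lo < res$or && res$or < res$ci_hi)
  # independence: OR ~ 1, CI covers 1
  set.seed(12)
  hi2 <- rbinom(4000, 1, 0.2)
  cls2 <- rbinom(4000, 1, 0.5)
  res2 <- enrichment_odds_ratio(hi2, cls2)
  expect_true(res2$ci_lo < 1 && 1 < res2$ci_hi)
  # zero cell triggers the Haldane-Anscombe correction
  res3 <- enrichment_odds_ratio(c(1, 1, 0, 0), factor(c("b", "b", "a", "a"),
                                                      levels = c("a", "b")))
  expect_true(res3$corrected)
  expect_true(is.finite(res3$or))
})

test_that("quantile-matched cutoffs transfer monotonely across score scales", {
  set.seed(13)
  ref <- runif(500)
  expect_equal(match_quantile_cutoff(ref, ref[17], ref), ref[17])
  # a doubled score scale doubles the cutoff
  expect_equal(match_quantile_cutoff(ref, 0.3, 2 * ref),
               2 * match_quantile_cutoff(ref, 0.3, ref), tolerance = 1e-12)
  # below-all-scores cutoff maps to the minimum side
  expect_equal(match_quantile_cutoff(ref, -1, 2 * ref), min(2 * ref))
  cuts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(cc)
    match_quantile_cutoff(ref, cc, 2 * ref), numeric(1))
  expect_true(all(diff(cuts) >= 0))
})

test_that("minimum-across-tissues collapses to the most impactful prediction", {
  dt <- data.table(variant_key = c("v1", "v1", "v1", "v2"),
                   tissue = c("a", "b", "c", "a"),
                   score = c(-1, -3, 0, 2))
  res <- min_across_tissues(dt)
  expect_equal(res[variant_key == "v1", min_score], -3)
  expect_equal(res[variant_key == "v2", min_score], 2)
  # brute force on a random table
  set.seed(14)
  big <- data.table(variant_key = sample(letters, 300, replace = TRUE),
                    score = rnorm(300))
  res2 <- min_across_tissues(big)
  for (k in res2$variant_key)
    expect_equal(res2[variant_key == k, min_score],
                 min(big$score[big$variant_key == k]))
})
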