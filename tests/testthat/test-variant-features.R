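make_variant <- function(key = "v1", ind = "I1", pos = 1000L, af = 0,
                         carriers = 1L, gq = 60L, dp = 30L, sv = FALSE,
                         sv_type = NA_character_, end = NA_integer_) {
  data.table(variant_key = key, individual_id = ind, chrom = "chr1",
             pos = pos, end = if (is.na(end)) pos else end,
             ref = "A", alt = "T",
             genotype_quality = gq, read_depth = dp, population_af = af,
             cohort_carrier_count = carriers, is_structural = sv,
             sv_type = sv_type)
}

test_that("rare-variant filtering enforces frequency, carrier and quality rules", {
  vs <- rbind(
    make_variant("pass"),
    make_variant("af_high", af = 0.002),
    make_variant("af_boundary", af = 0.001),
    make_variant("gq30", gq = 30L),          # strict GQ > 30
    make_variant("gq31", gq = 31L),
    make_variant("dp9", dp = 9L),
    make_variant("carriers3", carriers = 3L),
    make_variant("sv_kept", sv = TRUE, sv_type = "DEL", gq = NA_integer_,
                 dp = NA_integer_, carriers = 2L),
    make_variant("sv_common", sv = TRUE, sv_type = "DEL", carriers = 5L))
  out <- filter_rare_variants(vs)
  expect_setequal(out$variant_key, c("pass", "af_boundary", "gq31", "sv_kept"))
  # missing AF treated as rare
  vna <- make_variant("na_af")[, population_af := NA_real_]
  expect_equal(nrow(filter_rare_variants(vna)), 1L)
  # malformed quality fields on a small variant drop the record with a warning
  vbad <- make_variant("bad")[, genotype_quality := NA_integer_]
  expect_warning(res <- filter_rare_variants(rbind(make_variant("ok"), vbad)),
                 "malformed")
  expect_equal(res$variant_key, "ok")
})

toy_transcripts <- function() {
  data.table(gene_id = c("G1", "G1", "G2", "G3"),
             transcript_id = c("G1.T1", "G1.T2", "G2.T1", "G3.T1"),
             chrom = "chr1",
             start = c(100000L, 100000L, 500000L, 900000L),
             end = c(120000L, 115000L, 520000L, 950000L),
             strand = c("+", "+", "-", "+"),
             is_canonical = c(TRUE, FALSE, TRUE, TRUE))
}

test_that("variant-gene assignment respects the 5 kb window at its boundaries", {
  tx <- toy_transcripts()
  vs <- rbind(
    make_variant("v_in", pos = 110000L),
    make_variant("v_4999", pos = 100000L - 4999L),
    make_variant("v_5000", pos = 100000L - 5000L),
    make_variant("v_5001", pos = 100000L - 5001L),
    make_variant("v_down", pos = 120000L + 5000L))
  pairs <- assign_variants_to_genes(vs, tx)
  expect_setequal(pairs[gene_id == "G1", variant_key],
                  c("v_in", "v_4999", "v_5000", "v_down"))
  expect_false("v_5001" %in% pairs$variant_key)
})

test_that("structural variants pair through the strand-aware 1 Mb 5' window", {
  tx <- toy_transcripts()
  # G2 is on the minus strand: TSS at end = 520000, upstream extends rightwards
  sv_up_minus <- make_variant("sv_minus", pos = 900000L, end = 905000L,
                              sv = TRUE, sv_type = "DEL")
  # same interval relative to G1 (+): it is downstream, not 5'
  pairs <- assign_variants_to_genes(sv_up_minus, tx)
  expect_true("G2" %in% pairs$gene_id)
  # an SV 1 Mb + 1 beyond the plus-strand TSS of G3 does not pair with G3
  sv_far <- make_variant("sv_far", pos = 900000L - 1000001L,
                         end = 900000L - 1000001L, sv = TRUE, sv_type = "DEL")
  pairs2 <- assign_variants_to_genes(sv_far, tx)
  expect_false("G3" %in% pairs2$gene_id)
  # unknown contig skipped with a warning
  weird <- make_variant("v_weird")[, chrom := "chrZ"]
  expect_warning(p3 <- assign_variants_to_genes(weird, tx), "skipped")
  expect_equal(nrow(p3), 0L)
})

test_that("assignment equals an all-pairs interval scan on a toy instance", {
  tx <- toy_transcripts()
  set.seed(21)
  vs <- rbindlist(lapply(1:40, function(i)
    make_variant(paste0("v", i), ind = sample(c("I1", "I2"), 1),
                 pos = sample(90000:960000, 1))))
  pairs <- assign_variants_to_genes(vs, tx)
  genes <- tx[, .(start = min(start), end = max(end)), by = gene_id]
  expected <- rbindlist(lapply(seq_len(nrow(vs)), function(i) {
    hit <- genes[vs$pos[i] >= start - 5000 & vs$pos[i] <= end + 5000]
    if (nrow(hit)) data.table(variant_key = vs$variant_key[i],
                              individual_id = vs$individual_id[i],
                              gene_id = hit$gene_id)
  }))
  setorder(expected, variant_key, individual_id, gene_id)
  expect_equal(pairs, expected)
})

test_that("isoform proportions are medians of shares, renormalised per gene-tissue", {
  # single isoform: proportion 1 everywhere
  tpm1 <- CJ(gene_id = "G1", transcript_id = "G1.T1", tissue = c("a", "b"),
             individual_id = c("I1", "I2"))
  tpm1[, tpm := 5]
  p1 <- compute_isoform_proportions(tpm1)
  expect_true(all(p1$proportion == 1))

  # constant (3, 1) shares -> (0.75, 0.25)
  tpm2 <- CJ(transcript_id = c("G1.T1", "G1.T2"), tissue = "a",
             individual_id = c("I1", "I2", "I3"))
  tpm2[, gene_id := "G1"]
  tpm2[, tpm := ifelse(transcript_id == "G1.T1", 3, 1)]
  p2 <- compute_isoform_proportions(tpm2)
  expect_equal(p2[transcript_id == "G1.T1", proportion], 0.75)

  # hand computation: shares (0.2, 0.5, 0.8) -> median 0.5, renormalised
  tpm3 <- data.table(
    gene_id = "G1",
    transcript_id = rep(c("A", "B"), each = 3),
    tissue = "a",
    individual_id = rep(c("I1", "I2", "I3"), 2),
    tpm = c(2, 5, 8, 8, 5, 2))
  p3 <- compute_isoform_proportions(tpm3)
  expect_equal(p3[transcript_id == "A", proportion], 0.5)
  expect_equal(p3[, sum(proportion)], 1)

  # individuals with zero gene total are excluded from the median
  tpm4 <- copy(tpm3)
  tpm4 <- rbind(tpm4, data.table(gene_id = "G1", transcript_id = c("A", "B"),
                                 tissue = "a", individual_id = "I4", tpm = 0))
  expect_equal(compute_isoform_proportions(tpm4)[transcript_id == "A", proportion], 0.5)

  # fully silent gene emits missing proportions
  tpm5 <- data.table(gene_id = "G9", transcript_id = "G9.T1", tissue = "a",
                     individual_id = c("I1", "I2"), tpm = 0)
  expect_true(is.na(compute_isoform_proportions(tpm5)$proportion))

  # proportions sum to 1 per gene-tissue on random data
  set.seed(22)
  tpm6 <- CJ(transcript_id = paste0("T", 1:4), tissue = c("a", "b"),
             individual_id = paste0("I", 1:10))
  tpm6[, gene_id := "G1"]
  tpm6[, tpm := rexp(.N, 0.1)]
  sums <- compute_isoform_proportions(tpm6)[, sum(proportion), by = tissue]$V1
  expect_equal(sums, c(1, 1), tolerance = 1e-6)
})

test_that("isoform weights sum affected proportions and bound to [0, 1]", {
  pr <- data.table(gene_id = "G1", transcript_id = c("A", "B"),
                   tissue = "a", proportion = c(0.25, 0.75))
  expect_equal(isoform_weight("A", "G1", "a", pr), 0.25)
  expect_equal(isoform_weight(c("A", "B"), "G1", "a", pr), 1.0)
  expect_equal(isoform_weight(character(0), "G1", "a", pr), 0.0)
  expect_error(isoform_weight("A", "G1", "zz", pr), "canonical")
})

toy_feature_inputs <- function() {
  tx <- toy_transcripts()
  pr <- CJ(transcript_id = tx$transcript_id, tissue = c("a", "b"))
  pr <- merge(pr, tx[, .(transcript_id, gene_id)], by = "transcript_id")
  pr[, proportion := fifelse(gene_id != "G1", 1,
                             fifelse(transcript_id == "G1.T1",
                                     fifelse(tissue == "a", 0.3, 0.9),
                                     fifelse(tissue == "a", 0.7, 0.1)))]
  ann <- data.table(
    variant_key = c("v1", "v1", "v2", "v3"),
    transcript_id = c("G1.T1", "G1.T2", "G1.T1", "G2.T1"),
    consequence = c("stop_gained", "stop_gained", "stop_gained",
                    "missense_variant"),
    loftee = c("HC", "HC", "", ""),
    cadd = c(35, 35, 12, 22))
  pairs <- data.table(variant_key = c("v1", "v2", "v3"),
                      individual_id = c("I1", "I1", "I2"),
                      gene_id = c("G1", "G1", "G2"))
  list(tx = tx, pr = pr, ann = ann, pairs = pairs)
}

test_that("weighted aggregation takes the max weight across variants", {
  inp <- toy_feature_inputs()
  feats <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx,
                                   mode = "weighted", proportions = inp$pr,
                                   individuals = c("I1", "I2"))
  # v1 affects both isoforms (w = 1), v2 only T1 (w = 0.3 in a, 0.9 in b)
  expect_equal(feats[gene_id == "G1" & individual_id == "I1" & tissue == "a",
                     feat_stop_gained], 1)
  # CADD max across the gene's variants
  expect_equal(feats[gene_id == "G1" & individual_id == "I1" & tissue == "a",
                     cadd_max], 35)
  # all-zero row still emitted for untouched combinations
  zero_row <- feats[gene_id == "G3" & individual_id == "I1" & tissue == "a"]
  expect_equal(nrow(zero_row), 1L)
  expect_equal(zero_row$feat_stop_gained, 0)
  expect_equal(zero_row$cadd_max, 0)
  # weighted features bounded in [0, 1]
  fcols <- grep("^feat_", names(feats), value = TRUE)
  expect_true(all(as.matrix(feats[, fcols, with = FALSE]) >= 0))
  expect_true(all(as.matrix(feats[, fcols, with = FALSE]) <= 1))
})

test_that("single-isoform genes make weighted and canonical modes agree", {
  inp <- toy_feature_inputs()
  w <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx, mode = "weighted",
                               proportions = inp$pr, individuals = c("I1", "I2"))
  c_ <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx, mode = "canonical",
                                proportions = inp$pr, individuals = c("I1", "I2"))
  # G2 has a single isoform: identical rows in both modes
  fcols <- grep("^feat_", names(w), value = TRUE)
  expect_equal(w[gene_id == "G2", fcols, with = FALSE],
               c_[gene_id == "G2", fcols, with = FALSE])
})

test_that("aggregation is permutation/duplication invariant and matches brute force", {
  inp <- toy_feature_inputs()
  base <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx,
                                  mode = "weighted", proportions = inp$pr,
                                  individuals = c("I1", "I2"))
  shuf <- aggregate_gene_features(inp$pairs[c(3, 1, 2)],
                                  rbind(inp$ann[c(4, 2, 1, 3)], inp$ann[1]),
                                  inp$tx, mode = "weighted",
                                  proportions = inp$pr,
                                  individuals = c("I1", "I2"))
  expect_equal(base, shuf)

  for (md in c("weighted", "canonical")) {
    got <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx, mode = md,
                                   proportions = inp$pr,
                                   individuals = c("I1", "I2"))
    orc <- oracle_aggregate(inp$pairs, inp$ann, inp$tx, inp$pr, md,
                            tissues = c("a", "b"),
                            individuals = c("I1", "I2"),
                            genes = c("G1", "G2", "G3"))
    vocab <- c(consequence_vocabulary(), "LOFTEE_HC", "LOFTEE_LC")
    for (i in seq_len(nrow(orc))) {
      row <- got[gene_id == orc$gene_id[i] &
                 individual_id == orc$individual_id[i] &
                 tissue == orc$tissue[i]]
      for (tm in vocab)
        expect_equal(row[[paste0("feat_", tm)]], orc[i, tm],
                     info = paste(md, orc$gene_id[i], tm))
    }
  }
})

test_that("unknown consequence terms error or pool per configuration", {
  inp <- toy_feature_inputs()
  ann_bad <- copy(inp$ann)[1, consequence := "weird_term"]
  expect_error(aggregate_gene_features(inp$pairs, ann_bad, inp$tx,
                                       mode = "weighted",
                                       proportions = inp$pr), "unknown")
  ok <- aggregate_gene_features(inp$pairs, ann_bad, inp$tx, mode = "weighted",
                                proportions = inp$pr, unknown = "other",
                                individuals = c("I1", "I2"))
  expect_true("feat_other" %in% names(ok))
})

test_that("structural deletions covering a transcript yield ablation annotations", {
  tx <- toy_transcripts()
  sv <- make_variant("svdel", pos = 99000L, end = 130000L, sv = TRUE,
                     sv_type = "DEL")
  ann <- annotate_sv_ablation(sv, tx)
  expect_setequal(ann$transcript_id, c("G1.T1", "G1.T2"))
  expect_true(all(ann$consequence == "transcript_ablation"))
  # partial overlap is not ablation
  sv2 <- make_variant("svpart", pos = 110000L, end = 130000L, sv = TRUE,
                      sv_type = "DEL")
  expect_equal(nrow(annotate_sv_ablation(sv2, tx)), 0L)
})

test_that("absplice and bcv join into the feature table", {
  inp <- toy_feature_inputs()
  absp <- data.table(variant_key = c("v1", "v1"), tissue = c("a", "b"),
                     absplice = c(-0.8, 0.2))
  bcv <- CJ(gene_id = c("G1", "G2", "G3"), tissue = c("a", "b"))
  bcv[, bcv := 0.25]
  feats <- aggregate_gene_features(inp$pairs, inp$ann, inp$tx,
                                   mode = "weighted", proportions = inp$pr,
                                   individuals = c("I1", "I2"),
                                   bcv_table = bcv, absplice = absp)
  expect_equal(feats[gene_id == "G1" & individual_id == "I1" & tissue == "a",
                     absplice_max_abs], -0.8)
  expect_true(all(feats$bcv == 0.25))
  expect_setequal(feature_columns(feats),
                  c(grep("^feat_", names(feats), value = TRUE),
                    "cadd_max", "absplice_max_abs", "bcv"))
})
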