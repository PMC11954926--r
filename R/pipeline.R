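#' Run the full prediction pipeline on a (synthetic or real) cohort
#'
#' Convenience wrapper chaining the pipeline stages: rare-variant filtering,
#' variant-to-gene assignment, isoform-proportion computation, benchmark
#' construction, feature aggregation, grouped cross-validated training of the
#' z-score regressor, and out-of-fold evaluation. Expects a list with the
#' components produced by [simulate_cohort()] (`variants`, `transcripts`,
#' `annotations`, `tpm`, `outrider`).
#'
#' @param cohort List with `variants`, `transcripts`, `annotations`, `tpm`,
#'   `outrider`.
#' @param mode Feature aggregation mode (`"weighted"` or `"canonical"`).
#' @param config Model configuration ([abexp_config()]).
#' @param min_mu,fdr_cutoff,max_outliers_per_sample Benchmark filter
#'   parameters.
#' @return List with `benchmark`, `features`, `data` (features joined to
#'   targets), `folds`, `model`, `oof` (out-of-fold predictions with labels)
#'   and `auprc` (out-of-fold average precision for underexpression, ranking
#'   by ascending predicted z).
#' @export
run_cohort_pipeline <- function(cohort, mode = c("weighted", "canonical"),
                                config = abexp_config(),
                                min_mu = 450, fdr_cutoff = 0.05,
                                max_outliers_per_sample = 20) {
  mode <- match.arg(mode)
  rare <- filter_rare_variants(cohort$variants)
  pairs <- assign_variants_to_genes(rare, cohort$transcripts)
  props <- compute_isoform_proportions(cohort$tpm)
  bench <- apply_benchmark_filters(cohort$outrider, min_mu = min_mu,
                                   fdr_cutoff = fdr_cutoff,
                                   max_outliers_per_sample = max_outliers_per_sample)
  bcv_table <- unique(bench[, .(gene_id, tissue, bcv)])
  individuals <- sort(unique(cohort$outrider$individual_id))
  feats <- aggregate_gene_features(
    pairs, cohort$annotations, cohort$transcripts, mode = mode,
    proportions = props, tissues = sort(unique(cohort$outrider$tissue)),
    individuals = individuals, genes = sort(unique(cohort$transcripts$gene_id)),
    bcv_table = bcv_table)
  dat <- merge(feats, bench[, .(gene_id, individual_id, tissue, z, label)],
               by = c("gene_id", "individual_id", "tissue"))
  out_counts <- dat[, .(n_out = sum(label == "underexpression_outlier")),
                    by = individual_id]
  all_ind <- out_counts[data.table(individual_id = individuals),
                        on = "individual_id"]
  all_ind[is.na(n_out), n_out := 0L]
  folds <- make_cv_folds(all_ind$individual_id, all_ind$n_out,
                         n_folds = config$n_folds, seed = config$seed)
  model <- train_abexp(dat, dat$z, folds, config)
  oof <- copy(model$oof)
  oof[, label := dat$label]
  auprc <- average_precision(-oof$z_pred,
                             oof$label == "underexpression_outlier")
  list(benchmark = bench, features = feats, data = dat, folds = folds,
       model = model, oof = oof, auprc = auprc)
}
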