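#' @import data.table
#' @importFrom stats pnbinom qnorm dnbinom p.adjust median quantile sd rnorm
#'   runif rbinom rpois rnbinom rgamma complete.cases lm logLik pchisq glm
#'   binomial coef vcov predict fisher.test wilcox.test ks.test ecdf
#'   model.matrix setNames aggregate na.omit
#' @importFrom utils head tail
NULL

#' Biological coefficient of variation from a negative-binomial dispersion
#'
#' The BCV summarises the expression variability of a gene in a tissue beyond
#' counting noise: for an NB model with dispersion `theta` (variance
#' `mu + mu^2/theta`), BCV = 1/sqrt(theta).
#'
#' @param theta Positive NB dispersion parameter(s).
#' @return Non-negative numeric vector of the same length as `theta`.
#' @export
#' @examples
#' compute_bcv(4)    # 0.5
#' compute_bcv(100)  # 0.1
compute_bcv <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0))
    stop("`theta` must be a finite positive number")
  1 / sqrt(theta)
}

#' Log2 fold-change of observed versus expected fragment count
#'
#' Computes `log2(x + pseudocount) - log2(mu + pseudocount)`. With the default
#' pseudocount of 0 an observed count of zero yields `-Inf`; the return value
#' carries a logical attribute `"zero_flag"` marking those entries so callers
#' can handle the sentinel explicitly. A pseudocount of 1 gives a finite
#' alternative.
#'
#' @param x Non-negative observed count(s).
#' @param mu Positive expected count(s).
#' @param pseudocount Non-negative constant added to both counts (default 0).
#' @return Numeric vector; attribute `zero_flag` marks `-Inf` entries.
#' @export
compute_log2fc <- function(x, mu, pseudocount = 0) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(x < 0)) stop("`x` must be non-negative")
  if (pseudocount < 0) stop("`pseudocount` must be non-negative")
  out <- log2(x + pseudocount) - log2(mu + pseudocount)
  attr(out, "zero_flag") <- !is.finite(out)
  out
}

#' Quantile-map an NB-distributed count to a standard-normal z-score
#'
#' Maps the observed count through the fitted negative-binomial cumulative
#' distribution and then through the standard-normal quantile function:
#' `z = qnorm(clamp(CDF_NB(x | mu, theta), eps, 1 - eps))`. The NB is
#' parameterised by mean `mu` and dispersion `theta` (variance
#' `mu + mu^2/theta`). Clamping keeps z finite; negative z means the count is
#' below expectation (underexpression).
#'
#' @param x Non-negative count(s).
#' @param mu Positive expected count(s).
#' @param theta Positive dispersion(s).
#' @param clamp_eps CDF clamping epsilon in (0, 0.5); default 1e-16.
#' @return Finite numeric z-score(s), non-decreasing in `x`.
#' @export
#' @examples
#' nb_z_score(0, mu = 450, theta = 25)    # strongly negative
#' nb_z_score(450, mu = 450, theta = 25)  # near 0
nb_z_score <- function(x, mu, theta, clamp_eps = 1e-16) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("`theta` must be positive")
  if (any(x < 0)) stop("`x` must be non-negative")
  if (length(clamp_eps) != 1L || clamp_eps <= 0 || clamp_eps >= 0.5)
    stop("`clamp_eps` must be in (0, 0.5)")
  p <- pnbinom(x, size = theta, mu = mu)
  qnorm(pmin(pmax(p, clamp_eps), 1 - clamp_eps))
}

.bench_cols <- c("sample_id", "individual_id", "gene_id", "tissue",
                 "x", "mu", "theta", "fdr")

#' Validate an OUTRIDER-style result table
#'
#' Checks the column contract of the expression-observation table consumed by
#' [apply_benchmark_filters()]: one row per (sample, gene, tissue) with
#' observed count `x`, expected count `mu`, dispersion `theta` and adjusted
#' p-value `fdr`.
#'
#' @param records data.frame/data.table of observations.
#' @return The validated table as a `data.table` (invisibly copied).
#' @export
validate_outrider_records <- function(records) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) {
    for (cc in setdiff(.bench_cols, names(dt))) dt[, (cc) := numeric(0)]
    return(dt)
  }
  if (!"individual_id" %in% names(dt)) dt[, individual_id := sample_id]
  miss <- setdiff(.bench_cols, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$mu <= 0)) stop("`mu` must be positive")
  if (any(dt$theta <= 0)) stop("`theta` must be positive")
  if (any(dt$x < 0)) stop("`x` must be non-negative")
  if (any(dt$fdr < 0 | dt$fdr > 1)) stop("`fdr` must lie in [0, 1]")
  if (anyDuplicated(dt[, .(sample_id, gene_id, tissue)]))
    stop("(sample_id, gene_id) must be unique per tissue")
  dt
}

#' Build a labeled expression-outlier benchmark from outlier-caller results
#'
#' Applies the benchmark filters to an OUTRIDER-style table and labels each
#' observation:
#' \enumerate{
#'   \item observations with expected count `mu < min_mu` are removed
#'     (insufficient coverage to detect a two-fold reduction);
#'   \item observations with `fdr < fdr_cutoff` are labeled
#'     `underexpression_outlier` when z < 0 and `overexpression_outlier` when
#'     z > 0, all others `non_outlier`;
#'   \item every record of any RNA-seq sample (one (sample, tissue) library)
#'     carrying more than `max_outliers_per_sample` outlier labels is removed
#'     (such samples typically reflect a poor caller fit).
#' }
#' The output gains columns `z`, `bcv`, `l2fc`, `l2fc_zero` and `label` and is
#' sorted by (sample, gene, tissue). By default the per-sample outlier cap
#' counts under- and overexpression outliers together and is applied after the
#' coverage filter; both choices are configurable.
#'
#' @param records OUTRIDER-style table (see [validate_outrider_records()]).
#' @param min_mu Minimum expected fragment count (default 450).
#' @param fdr_cutoff FDR threshold for outlier labels (default 0.05).
#' @param max_outliers_per_sample Samples with more outliers than this are
#'   dropped entirely (default 20).
#' @param count_outliers One of `"both"` (default), `"under"`: which labels
#'   count toward the per-sample cap.
#' @param cap_before_mu_filter Apply the outlier cap on the unfiltered table
#'   (default `FALSE`: cap is computed after the `mu` filter).
#' @param clamp_eps Passed to [nb_z_score()].
#' @param pseudocount Passed to [compute_log2fc()].
#' @return `data.table` of benchmark records with labels.
#' @export
apply_benchmark_filters <- function(records, min_mu = 450, fdr_cutoff = 0.05,
                                    max_outliers_per_sample = 20,
                                    count_outliers = c("both", "under"),
                                    cap_before_mu_filter = FALSE,
                                    clamp_eps = 1e-16, pseudocount = 0) {
  count_outliers <- match.arg(count_outliers)
  dt <- validate_outrider_records(records)
  if (nrow(dt) == 0L) {
    dt[, `:=`(z = numeric(0), bcv = numeric(0), l2fc = numeric(0),
              l2fc_zero = logical(0), label = character(0))]
    return(dt[])
  }
  dt <- copy(dt)
  dt[, z := nb_z_score(x, mu, theta, clamp_eps = clamp_eps)]
  dt[, bcv := compute_bcv(theta)]
  l2 <- compute_log2fc(dt$x, dt$mu, pseudocount = pseudocount)
  dt[, l2fc := as.numeric(l2)]
  dt[, l2fc_zero := attr(l2, "zero_flag")]
  dt[, label := "non_outlier"]
  dt[fdr < fdr_cutoff & z < 0, label := "underexpression_outlier"]
  dt[fdr < fdr_cutoff & z > 0, label := "overexpression_outlier"]

  if (!cap_before_mu_filter) dt <- dt[mu >= min_mu]
  counted <- if (count_outliers == "both")
    c("underexpression_outlier", "overexpression_outlier")
  else "underexpression_outlier"
  n_out <- dt[, .(n_out = sum(label %in% counted)), by = .(sample_id, tissue)]
  bad <- n_out[n_out > max_outliers_per_sample, .(sample_id, tissue)]
  if (nrow(bad)) dt <- dt[!bad, on = c("sample_id", "tissue")]
  if (cap_before_mu_filter) dt <- dt[mu >= min_mu]
  setorder(dt, sample_id, gene_id, tissue)
  dt[]
}

#' Summarise a labeled benchmark
#'
#' Counts outliers, non-outliers, samples and genes and derives the outlier
#' fraction (outliers / assessable gene-sample pairs) and the mean number of
#' underexpression outliers per sample. Fractions are `NA` on an empty
#' benchmark.
#'
#' @param benchmark Labeled table from [apply_benchmark_filters()].
#' @return A list of class `abexp_benchmark_summary`.
#' @export
benchmark_summary <- function(benchmark) {
  dt <- as.data.table(benchmark)
  n_under <- sum(dt$label == "underexpression_outlier")
  n_over <- sum(dt$label == "overexpression_outlier")
  n_non <- sum(dt$label == "non_outlier")
  n_samples <- if (nrow(dt)) uniqueN(dt[, .(sample_id, tissue)]) else 0L
  n_genes <- if (nrow(dt)) uniqueN(dt$gene_id) else 0L
  summarize_benchmark_counts(n_under, n_non, n_samples,
                             n_over = n_over, n_genes = n_genes)
}

#' Benchmark summary statistics from plain counts
#'
#' Pure-arithmetic form of [benchmark_summary()], useful when only published
#' aggregate counts of a benchmark are available: the outlier fraction is
#' outliers / (outliers + non-outliers) and the per-sample rate is
#' outliers / samples. Optionally derives the fraction of genes with
#' sufficient coverage from gene counts.
#'
#' @param n_outliers Number of underexpression outliers.
#' @param n_non_outliers Number of non-outlier gene-sample pairs.
#' @param n_samples Number of RNA-seq samples.
#' @param n_over Number of overexpression outliers (default 0).
#' @param n_genes Number of distinct genes in the benchmark (optional).
#' @param n_genes_covered,n_genes_total Genes with sufficient coverage in at
#'   least one tissue, out of all genes considered (optional).
#' @return List of class `abexp_benchmark_summary` with counts,
#'   `outlier_fraction`, `outlier_fraction_pct`, `outliers_per_sample` and,
#'   when gene counts are given, `covered_gene_pct`.
#' @export
#' @examples
#' s <- summarize_benchmark_counts(11200, 99434253, 10999,
#'                                 n_genes_covered = 18171, n_genes_total = 18563)
#' round(s$outlier_fraction_pct, 2)  # 0.01
#' round(s$outliers_per_sample, 2)   # 1.02
#' round(s$covered_gene_pct, 1)      # 97.9
summarize_benchmark_counts <- function(n_outliers, n_non_outliers, n_samples,
                                       n_over = 0L, n_genes = NA_integer_,
                                       n_genes_covered = NA_integer_,
                                       n_genes_total = NA_integer_) {
  tot <- n_outliers + n_non_outliers
  out <- list(
    n_outliers = n_outliers,
    n_overexpression_outliers = n_over,
    n_non_outliers = n_non_outliers,
    n_samples = n_samples,
    n_genes = n_genes,
    outlier_fraction = if (tot > 0) n_outliers / tot else NA_real_,
    outlier_fraction_pct = if (tot > 0) 100 * n_outliers / tot else NA_real_,
    outliers_per_sample = if (n_samples > 0) n_outliers / n_samples else NA_real_,
    covered_gene_pct = if (!is.na(n_genes_covered) && !is.na(n_genes_total) &&
                           n_genes_total > 0)
      100 * n_genes_covered / n_genes_total else NA_real_
  )
  class(out) <- "abexp_benchmark_summary"
  out
}

#' @export
print.abexp_benchmark_summary <- function(x, ...) {
  cat("Benchmark summary\n")
  cat(sprintf("  underexpression outliers: %s\n", format(x$n_outliers, big.mark = ",")))
  cat(sprintf("  non-outliers:             %s\n", format(x$n_non_outliers, big.mark = ",")))
  cat(sprintf("  samples: %s   genes: %s\n",
              format(x$n_samples, big.mark = ","), format(x$n_genes, big.mark = ",")))
  if (!is.na(x$outlier_fraction_pct))
    cat(sprintf("  outlier fraction: %.4f%%\n", x$outlier_fraction_pct))
  if (!is.na(x$outliers_per_sample))
    cat(sprintf("  outliers per sample: %.2f\n", x$outliers_per_sample))
  if (!is.na(x$covered_gene_pct))
    cat(sprintf("  genes with sufficient coverage: %.1f%%\n", x$covered_gene_pct))
  invisible(x)
}

#' Read an OUTRIDER-style result table from TSV
#'
#' Column names are remapped to the internal contract; the default mapping
#' accepts the conventional `sampleID`/`geneID`/`rawcounts`/`normcounts`/
#' `padjust` headers.
#'
#' @param path TSV file path.
#' @param col_map Named character vector `internal = file_column`.
#' @return Validated `data.table` of observations.
#' @export
read_outrider_tsv <- function(path,
                              col_map = c(sample_id = "sampleID",
                                          gene_id = "geneID",
                                          tissue = "tissue",
                                          x = "rawcounts",
                                          mu = "normcounts",
                                          theta = "theta",
                                          fdr = "padjust")) {
  dt <- fread(path, sep = "\t")
  for (internal in names(col_map)) {
    fc <- col_map[[internal]]
    if (fc %in% names(dt)) setnames(dt, fc, internal)
  }
  validate_outrider_records(dt)
}

#' Write a labeled benchmark table to TSV
#'
#' @param benchmark Table from [apply_benchmark_filters()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_benchmark_tsv <- function(benchmark, path) {
  fwrite(as.data.table(benchmark), path, sep = "\t")
  invisible(path)
}

#' Flag genes insufficiently expressed by the FPKM rule
#'
#' Reimplementation (for synthetic data) of the upstream expression filter
#' applied by outlier callers: a gene fails in a tissue when its FPKM is below
#' `min_fpkm` in at least `frac` of the samples. Real pipelines are expected
#' to have applied this before outlier calling.
#'
#' @param fpkm Matrix genes x samples of FPKM values for one tissue.
#' @param min_fpkm FPKM threshold (default 1).
#' @param frac Fraction of samples below threshold that fails the gene
#'   (default 0.95).
#' @return Logical vector, `TRUE` for sufficiently expressed genes.
#' @export
fpkm_expressed_filter <- function(fpkm, min_fpkm = 1, frac = 0.95) {
  below <- rowMeans(fpkm < min_fpkm)
  below < frac
}
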