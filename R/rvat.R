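#' Inverse rank-normal transformation
#'
#' Maps values to standard-normal quantiles of their (average, for ties)
#' ranks: `qnorm((rank - 0.5) / n)`, computed over non-missing values;
#' missing values propagate. Any monotone transform of the input yields the
#' same output, which makes downstream linear-model tests robust to skewed
#' trait scales.
#'
#' @param values Numeric vector (>= 3 non-missing, non-constant).
#' @return Transformed vector, same length, `NA`s preserved.
#' @export
inverse_rank_normal <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  if (length(unique(v)) == 1L) stop("constant trait cannot be rank-normalised")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 0.5) / length(v))
  out
}

#' Gene-level rare-variant burden encodings
#'
#' Collapses per-variant, per-tissue underexpression scores (or LOFTEE
#' loss-of-function flags) into the burden encodings used for association
#' testing:
#' \describe{
#'   \item{loftee_count}{number of the individual's rare LOFTEE variants in
#'     the gene (one column).}
#'   \item{abexp_all_tissues}{per-tissue minimum score across the
#'     individual's rare variants in the gene, 0 without any rare variant
#'     (one column per tissue).}
#'   \item{abexp_min / abexp_median}{minimum / median of those per-tissue
#'     values (one column).}
#' }
#'
#' @param variant_scores Table with `individual_id`, `gene_id`, and either
#'   per-variant per-tissue scores (`variant_key`, `tissue`, `score`) or a
#'   logical `loftee` flag per variant.
#' @param individuals All individuals to emit (zero-filled when absent).
#' @param scheme One of `"loftee_count"`, `"abexp_all_tissues"`,
#'   `"abexp_min"`, `"abexp_median"`.
#' @param gene Optional single gene to restrict to.
#' @return `data.table`, one row per individual (and gene), burden columns
#'   named `burden_*`.
#' @export
build_gene_burden <- function(variant_scores, individuals,
                              scheme = c("abexp_all_tissues", "abexp_min",
                                         "abexp_median", "loftee_count"),
                              gene = NULL) {
  scheme <- match.arg(scheme)
  dt <- as.data.table(variant_scores)
  if (!is.null(gene)) dt <- dt[gene_id %in% gene]
  genes <- if (!is.null(gene)) gene else unique(dt$gene_id)
  grid <- CJ(individual_id = individuals, gene_id = genes, unique = TRUE)
  if (scheme == "loftee_count") {
    cnt <- dt[loftee == TRUE,
              .(burden_loftee = uniqueN(variant_key)),
              by = .(individual_id, gene_id)]
    out <- merge(grid, cnt, by = c("individual_id", "gene_id"), all.x = TRUE)
    out[is.na(burden_loftee), burden_loftee := 0]
    return(out[])
  }
  tissues <- sort(unique(dt$tissue))
  per_tissue <- dt[, .(m = min(score)), by = .(individual_id, gene_id, tissue)]
  wide <- dcast(per_tissue, individual_id + gene_id ~ tissue, value.var = "m")
  out <- merge(grid, wide, by = c("individual_id", "gene_id"), all.x = TRUE)
  for (tt in tissues) out[is.na(get(tt)), (tt) := 0]
  if (scheme == "abexp_all_tissues") {
    setnames(out, tissues, paste0("burden_", tissues))
    return(out[])
  }
  M <- as.matrix(out[, tissues, with = FALSE])
  val <- if (scheme == "abexp_min") apply(M, 1, min) else apply(M, 1, median)
  out <- out[, .(individual_id, gene_id)]
  out[, (paste0("burden_", sub("abexp_", "", scheme))) := val]
  out[]
}

#' Likelihood-ratio association test of a gene burden with a trait
#'
#' Compares a restricted Gaussian linear model (trait ~ covariates) against
#' the full model adding the burden column(s) by a likelihood-ratio test with
#' the error variance profiled out (OLS maximum likelihood). Collinear burden
#' columns are dropped (with a warning) and the degrees of freedom adjusted
#' to the number of columns actually adding rank.
#'
#' @param trait Numeric response (typically rank-normalised).
#' @param covariates Numeric matrix/data.frame of covariates (without
#'   intercept; one is added).
#' @param burden Numeric vector or matrix of burden predictor(s).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_association <- function(trait, covariates, burden) {
  cov_m <- as.matrix(covariates)
  bur_m <- as.matrix(burden)
  if (nrow(cov_m) != length(trait) || nrow(bur_m) != length(trait))
    stop("row mismatch between trait, covariates and burden")
  fit0 <- lm(trait ~ cov_m)
  fit1 <- lm(trait ~ cov_m + bur_m)
  df <- fit1$rank - fit0$rank
  if (df < ncol(bur_m))
    warning("collinear burden column(s) dropped; df adjusted to ", df)
  if (df == 0L) return(list(statistic = 0, df = 0L, p_value = 1))
  stat <- 2 * (as.numeric(logLik(fit1)) - as.numeric(logLik(fit0)))
  stat <- max(stat, 0)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Calibration of burden tests under a permuted phenotype
#'
#' Permutes the phenotype once (seeded) and recomputes the per-gene LRT
#' p-values; under this null the p-values should be uniform. Returns the
#' Kolmogorov-Smirnov distance and p-value against Uniform(0, 1) and the
#' per-gene p-values for QQ inspection.
#'
#' @param trait Numeric response.
#' @param covariates Covariate matrix.
#' @param burdens Named list of burden vectors/matrices, one per gene.
#' @param seed Permutation seed.
#' @return List with `p_values`, `ks_distance`, `ks_p`.
#' @export
calibration_check <- function(trait, covariates, burdens, seed = 1L) {
  if (length(burdens) == 0L) stop("no genes supplied")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(trait)
  pv <- vapply(burdens, function(b)
    lrt_association(perm, covariates, b)$p_value, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  list(p_values = pv, ks_distance = unname(ks$statistic), ks_p = ks$p.value)
}

#' Held-out phenotype prediction with gene burden features
#'
#' Splits individuals into a discovery set (default two thirds) and a
#' prediction set. Trait-associated genes are discovered on the discovery set
#' by per-gene LRT with a Bonferroni threshold; the prediction set is then
#' modelled with `n_folds`-fold cross-validation using covariates alone
#' (baseline) and covariates plus the discovered genes' burdens. Reported per
#' model: held-out R-squared and, against the baseline, the number of
#' individuals whose absolute prediction error improves or worsens by more
#' than one trait standard deviation.
#'
#' @param trait Numeric response per individual.
#' @param covariates Covariate matrix (rows = individuals).
#' @param burdens Named list (per gene) of burden vectors/matrices aligned to
#'   individuals.
#' @param individuals Individual ids (rows).
#' @param learner `"regularized_linear"` (ridge; default) or
#'   `"boosted_trees"`.
#' @param discovery_fraction Fraction of individuals used for gene discovery
#'   (default 2/3).
#' @param alpha Family-wise error level for Bonferroni discovery (default
#'   0.05).
#' @param n_folds Cross-validation folds on the prediction set (default 5).
#' @param ridge_lambda Penalty for the linear learner (default 1e-3).
#' @param seed Split/shuffle seed.
#' @return List with `discovered_genes`, `r2_full`, `r2_baseline`,
#'   `n_improved`, `n_worsened`, `predictions`.
#' @export
phenotype_predict <- function(trait, covariates, burdens, individuals,
                              learner = c("regularized_linear", "boosted_trees"),
                              discovery_fraction = 2 / 3, alpha = 0.05,
                              n_folds = 5, ridge_lambda = 1e-3, seed = 1L) {
  learner <- match.arg(learner)
  n <- length(trait)
  cov_m <- as.matrix(covariates)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  disc_idx <- sort(sample.int(n, size = round(discovery_fraction * n)))
  pred_idx <- setdiff(seq_len(n), disc_idx)
  if (length(intersect(disc_idx, pred_idx)))
    stop("discovery and prediction individuals overlap")

  pv <- vapply(burdens, function(b) {
    bm <- as.matrix(b)
    lrt_association(trait[disc_idx], cov_m[disc_idx, , drop = FALSE],
                    bm[disc_idx, , drop = FALSE])$p_value
  }, numeric(1))
  thr <- alpha / length(burdens)
  discovered <- names(pv)[pv < thr]

  bur_cols <- if (length(discovered))
    do.call(cbind, lapply(burdens[discovered], as.matrix)) else NULL
  y <- trait[pred_idx]
  Xb <- cov_m[pred_idx, , drop = FALSE]
  Xf <- if (is.null(bur_cols)) Xb else cbind(Xb, bur_cols[pred_idx, , drop = FALSE])

  fold <- sample(rep(seq_len(n_folds), length.out = length(pred_idx)))
  pred_base <- pred_full <- rep(NA_real_, length(pred_idx))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    pred_base[!tr] <- .fit_predict(Xb[tr, , drop = FALSE], y[tr],
                                   Xb[!tr, , drop = FALSE], learner,
                                   ridge_lambda, seed + k)
    pred_full[!tr] <- .fit_predict(Xf[tr, , drop = FALSE], y[tr],
                                   Xf[!tr, , drop = FALSE], learner,
                                   ridge_lambda, seed + k)
  }
  sst <- sum((y - mean(y))^2)
  r2 <- function(p) 1 - sum((y - p)^2) / sst
  err_base <- abs(y - pred_base); err_full <- abs(y - pred_full)
  sdy <- sd(y)
  list(discovered_genes = discovered,
       r2_baseline = r2(pred_base), r2_full = r2(pred_full),
       n_improved = sum(err_base - err_full > sdy),
       n_worsened = sum(err_full - err_base > sdy),
       predictions = data.table(individual_id = individuals[pred_idx],
                                y = y, baseline = pred_base, full = pred_full))
}

.fit_predict <- function(Xtr, ytr, Xte, learner, lambda, seed) {
  if (learner == "boosted_trees") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bst <- xgboost::xgb.train(params = .xgb_params(abexp_config(seed = seed)),
                              data = xgboost::xgb.DMatrix(Xtr, label = ytr),
                              nrounds = 100, verbose = 0)
    predict(bst, xgboost::xgb.DMatrix(Xte))
  } else {
    fit <- ridge_fit(Xtr, ytr, lambda = lambda)
    ridge_predict(fit, Xte)
  }
}
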