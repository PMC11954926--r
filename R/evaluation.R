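#' Average precision of a ranking
#'
#' Area under the precision-recall curve computed as recall-weighted
#' precision, `AP = sum_n (R_n - R_{n-1}) P_n`, sweeping thresholds over
#' descending scores. Ties are grouped: all rows sharing a score enter the
#' confusion matrix together, so AP does not depend on the ordering of tied
#' rows. This is the summary of choice under extreme class imbalance, where
#' ROC curves are dominated by the majority class.
#'
#' @param scores Numeric scores, larger = more confidently positive.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AP in (0, 1].
#' @export
#' @examples
#' average_precision(c(4, 3, 2, 1), c(0, 1, 0, 1))  # 0.5
average_precision <- function(scores, labels) {
  pr <- pr_curve(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Precision-recall curve
#'
#' One operating point per distinct score value (descending); recall is
#' non-decreasing along the curve.
#'
#' @inheritParams average_precision
#' @return `data.table` with columns `threshold`, `n_predicted`, `precision`,
#'   `recall`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(!labels %in% c(0L, 1L))) stop("labels must be binary")
  npos <- sum(labels)
  if (npos == 0L) stop("at least one positive label is required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores into one threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_group]
  n_pred <- seq_along(s)[last_of_group]
  data.table(threshold = s[last_of_group],
             n_predicted = n_pred,
             precision = tp / n_pred,
             recall = tp / npos)
}

#' Precision and recall when predicting positives below/above a score cutoff
#'
#' @inheritParams average_precision
#' @param cutoff Score threshold; rows with `scores >= cutoff` are predicted
#'   positive.
#' @return List with `precision`, `recall`, `n_predicted`.
#' @export
precision_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  pred <- scores >= cutoff
  tp <- sum(labels == 1L & pred)
  list(precision = if (sum(pred)) tp / sum(pred) else NA_real_,
       recall = tp / sum(labels == 1L),
       n_predicted = sum(pred))
}

#' Average precision per tissue type
#'
#' Tissues are grouped into broader tissue types (e.g. the many brain regions
#' of GTEx form one type) and an AP is computed on each type's pooled rows, so
#' that overrepresented, highly similar tissues do not dominate a model
#' comparison. Types without a positive are reported as `NA`.
#'
#' @param predictions Table with columns `score`, `label`, `tissue`.
#' @param tissue_type_map Table mapping `tissue` to `tissue_type`; the shipped
#'   default covers the 49 GTEx tissues in 27 types (see
#'   [gtex_tissue_types()]).
#' @return `data.table` with `tissue_type` and `auprc`.
#' @export
per_tissue_type_auprc <- function(predictions, tissue_type_map = gtex_tissue_types()) {
  dt <- as.data.table(predictions)
  map <- as.data.table(tissue_type_map)
  unmapped <- setdiff(unique(dt$tissue), map$tissue)
  if (length(unmapped))
    stop("tissues missing from the tissue-type map: ",
         paste(unmapped, collapse = ", "))
  dt <- map[dt, on = "tissue"]
  dt[, .(auprc = if (sum(label) > 0) average_precision(score, label)
         else NA_real_),
     by = tissue_type][order(tissue_type)]
}

#' The shipped GTEx 49-tissue to 27-tissue-type grouping
#'
#' @return `data.table` with columns `tissue`, `tissue_type`.
#' @export
gtex_tissue_types <- function() {
  path <- system.file("extdata", "gtex_tissue_types.tsv", package = "abexp")
  fread(path, sep = "\t")
}

#' Paired comparison of per-tissue-type performance between two models
#'
#' Two-sided paired Wilcoxon signed-rank test on per-type AP vectors. The
#' exact null distribution is used when there are no ties/zeros and n < 50
#' (the default of [stats::wilcox.test()]); an all-zero difference vector
#' returns p = 1 by convention.
#'
#' @param ap_a,ap_b Named or parallel numeric vectors of per-type AP.
#' @return List with `p_value`, `statistic`, `n`.
#' @export
paired_model_comparison <- function(ap_a, ap_b) {
  if (!is.null(names(ap_a)) && !is.null(names(ap_b))) {
    common <- intersect(names(ap_a), names(ap_b))
    if (length(common) != length(ap_a) || length(common) != length(ap_b))
      stop("ap_a and ap_b must cover the same tissue types")
    ap_b <- ap_b[names(ap_a)]
  }
  if (length(ap_a) != length(ap_b)) stop("vectors differ in length")
  keep <- is.finite(ap_a) & is.finite(ap_b)
  d <- ap_a[keep] - ap_b[keep]
  if (all(d == 0)) return(list(p_value = 1, statistic = NA_real_, n = sum(keep)))
  wt <- suppressWarnings(wilcox.test(ap_a[keep], ap_b[keep], paired = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), n = sum(keep))
}

#' Consequence classes used for outlier attribution
#'
#' Groups VEP-style consequence terms into the broader classes used when
#' attributing outliers to their most impactful variant class.
#'
#' @return Named character vector mapping consequence term to class.
#' @export
consequence_class_map <- function() {
  c(stop_gained = "NMD-like", frameshift_variant = "NMD-like",
    start_lost = "NMD-like", stop_lost = "NMD-like",
    NMD_escaping = "NMD-like",
    splice_acceptor_variant = "Splicing disruption",
    splice_donor_variant = "Splicing disruption",
    splice_region_variant = "Splicing disruption",
    transcript_ablation = "Structural ablation",
    upstream_gene_variant = "Promoter",
    `5_prime_UTR_variant` = "UTR", `3_prime_UTR_variant` = "UTR",
    intron_variant = "Intron",
    inframe_deletion = "Inframe CDS", inframe_insertion = "Inframe CDS",
    missense_variant = "Inframe CDS",
    synonymous_variant = "Synonymous",
    downstream_gene_variant = "Downstream")
}

#' Assign each observation to its most impactful consequence class
#'
#' For every consequence class a Fisher's exact test of class presence against
#' outlier status is computed; classes are ordered by decreasing significance
#' (ties broken by a fixed class order), and each row is assigned the most
#' significant class present among its consequences. Rows with no annotated
#' class get `NA`.
#'
#' @param consequence_sets List of character vectors of consequence terms (or
#'   classes), one per row.
#' @param outlier Binary outlier status per row.
#' @param alternative Sidedness of the Fisher tests (default two-sided).
#' @return List with `assigned` (character per row) and `ordering`
#'   (`data.table` of class, p-value).
#' @export
assign_consequence_class <- function(consequence_sets, outlier,
                                     alternative = "two.sided") {
  map <- consequence_class_map()
  classes_per_row <- lapply(consequence_sets, function(terms) {
    cls <- ifelse(terms %in% names(map), map[terms], terms)
    unique(unname(cls))
  })
  fixed_order <- c("NMD-like", "Splicing disruption", "Structural ablation",
                   "Promoter", "UTR", "Intron", "Inframe CDS", "Synonymous",
                   "Downstream")
  outlier <- as.integer(outlier)
  present <- sort(unique(unlist(classes_per_row)))
  if (length(present) == 0L)
    return(list(assigned = rep(NA_character_, length(outlier)),
                ordering = data.table(class = character(0), p = numeric(0))))
  pvals <- vapply(present, function(cl) {
    has <- vapply(classes_per_row, function(x) cl %in% x, logical(1))
    tab <- table(factor(has, levels = c(TRUE, FALSE)),
                 factor(outlier, levels = c(1L, 0L)))
    fisher.test(tab, alternative = alternative)$p.value
  }, numeric(1))
  rank_in_fixed <- match(present, fixed_order)
  rank_in_fixed[is.na(rank_in_fixed)] <- length(fixed_order) + 1L
  ordering <- data.table(class = present, p = pvals)[
    order(p, rank_in_fixed)]
  assigned <- vapply(classes_per_row, function(x) {
    if (length(x) == 0L) return(NA_character_)
    ordering$class[min(match(x, ordering$class), na.rm = TRUE)]
  }, character(1))
  list(assigned = assigned, ordering = ordering)
}

#' Enrichment odds ratio of high-impact calls across variant classes
#'
#' Logistic regression of a binary high-impact indicator on a class variable
#' (binary or factor, e.g. allele-frequency category or LOEUF decile);
#' coefficients are exponentiated into odds ratios with Wald 95% CIs. For a
#' single binary predictor the OR equals the 2x2 cross-product ratio. When a
#' cell of the implied table is empty, a Haldane-Anscombe 0.5 correction is
#' applied to the 2x2 table and the result flagged.
#'
#' @param high_impact Binary vector.
#' @param class_indicator Binary vector or factor.
#' @return `data.table` with one row per non-reference level: `level`, `or`,
#'   `ci_lo`, `ci_hi`, `corrected`.
#' @export
enrichment_odds_ratio <- function(high_impact, class_indicator) {
  y <- as.integer(high_impact)
  f <- if (is.factor(class_indicator)) class_indicator else factor(class_indicator)
  lv <- levels(f)
  res <- lapply(lv[-1], function(l) {
    sub <- f %in% c(lv[1], l)
    x <- as.integer(f[sub] == l)
    yy <- y[sub]
    tab <- table(factor(x, 0:1), factor(yy, 0:1))
    if (any(tab == 0)) {
      tab2 <- tab + 0.5
      or <- (tab2["1", "1"] * tab2["0", "0"]) / (tab2["1", "0"] * tab2["0", "1"])
      se <- sqrt(sum(1 / tab2))
      data.table(level = l, or = or,
                 ci_lo = exp(log(or) - 1.96 * se),
                 ci_hi = exp(log(or) + 1.96 * se), corrected = TRUE)
    } else {
      fit <- glm(yy ~ x, family = binomial())
      b <- coef(fit)[["x"]]
      se <- sqrt(vcov(fit)["x", "x"])
      data.table(level = l, or = exp(b),
                 ci_lo = exp(b - 1.96 * se),
                 ci_hi = exp(b + 1.96 * se), corrected = FALSE)
    }
  })
  rbindlist(res)
}

#' Transfer a score cutoff to another score by quantile matching
#'
#' Returns the empirical quantile of `other_scores` at the quantile that
#' `reference_cutoff` occupies within `reference_scores`. Used to compare
#' methods at operating points of equal call rate.
#'
#' @param reference_scores,other_scores Numeric score vectors.
#' @param reference_cutoff Cutoff on the reference score.
#' @return Cutoff on the other score.
#' @export
match_quantile_cutoff <- function(reference_scores, reference_cutoff,
                                  other_scores) {
  if (!length(reference_scores) || !length(other_scores))
    stop("score vectors must be non-empty")
  p <- mean(reference_scores <= reference_cutoff)
  if (p == 0) return(min(other_scores))
  unname(quantile(other_scores, probs = p, type = 1))
}

#' Minimum predicted score across tissues
#'
#' Collapses per-tissue predictions to the most impactful (most negative)
#' underexpression prediction per key, as used for variant-level evaluation
#' against pathogenicity databases.
#'
#' @param predictions Table with a `score` column and key columns.
#' @param by Key column names (default `"variant_key"`; any id columns work).
#' @return `data.table` of keys and `min_score`.
#' @export
min_across_tissues <- function(predictions, by = "variant_key") {
  dt <- as.data.table(predictions)
  dt[, .(min_score = min(score)), by = by]
}
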