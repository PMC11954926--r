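#' Ridge (or OLS) linear fit by normal equations
#'
#' Solves `argmin ||y - b0 - X b||^2 + lambda ||b||^2` with an unpenalised
#' intercept via centering, or without intercept the plain
#' `(X'X + lambda I)^-1 X'y` solution. With `lambda = 0` an OLS fit via QR is
#' used; a rank-deficient design with zero penalty is an error.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param lambda Non-negative L2 penalty (default 0).
#' @param intercept Fit an unpenalised intercept (default TRUE).
#' @return List of class `abexp_ridge` with `coef`, `intercept`, `lambda`.
#' @export
ridge_fit <- function(X, y, lambda = 0, intercept = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) {
    if (!intercept) stop("empty design without intercept")
    return(structure(list(coef = numeric(0), intercept = mean(y),
                          lambda = lambda, center = numeric(0)),
                     class = "abexp_ridge"))
  }
  if (lambda < 0) stop("lambda must be non-negative")
  if (intercept) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm); yc <- y - ym
  } else {
    xm <- rep(0, ncol(X)); ym <- 0
    Xc <- X; yc <- y
  }
  if (lambda == 0) {
    qr_x <- qr(Xc)
    if (qr_x$rank < ncol(Xc))
      stop("rank-deficient design with zero penalty; increase lambda")
    b <- qr.coef(qr_x, yc)
  } else {
    b <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, yc))
  }
  b <- drop(b)
  structure(list(coef = b, intercept = ym - sum(xm * b), lambda = lambda),
            class = "abexp_ridge")
}

#' @rdname ridge_fit
#' @param fit An `abexp_ridge` object.
#' @export
ridge_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (length(fit$coef) == 0L) return(rep(fit$intercept, nrow(X)))
  drop(X %*% fit$coef) + fit$intercept
}

#' Expression target from transcript-level TPM
#'
#' The regression target for sequence-based expression mapping:
#' `y = log10(1 + mean_individuals(TPM))` per transcript and tissue.
#'
#' @param tpm Numeric vector of per-individual TPM values for one transcript
#'   and tissue.
#' @return Scalar target value.
#' @export
#' @examples
#' expression_target(rep(9, 10))  # 1
expression_target <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be non-negative")
  log10(1 + mean(tpm))
}

#' Map aggregated sequence-model track predictions to tissue expression
#'
#' Fits a (ridge-)regularised linear model predicting the expression target
#' from `log10(1 + u)`-transformed track aggregates, one model per tissue:
#' `y = beta' log10(1 + u) + intercept`. The aggregates `u` are consumed as a
#' non-negative matrix (one row per sequence, one column per track); how they
#' were produced (which sequence model, shifts and bins were averaged) is
#' upstream of this package.
#'
#' @param u Non-negative matrix of track aggregates (rows = sequences).
#' @param y Expression targets (from [expression_target()]).
#' @param lambda Ridge penalty (default 0 = OLS).
#' @param intercept Fit an intercept (default TRUE).
#' @return List of class `abexp_track_mapping` wrapping the linear fit.
#' @export
fit_expression_mapping <- function(u, y, lambda = 0, intercept = TRUE) {
  u <- as.matrix(u)
  if (any(u < 0)) stop("track aggregates must be non-negative")
  fit <- ridge_fit(log10(1 + u), y, lambda = lambda, intercept = intercept)
  structure(list(fit = fit), class = "abexp_track_mapping")
}

#' @rdname fit_expression_mapping
#' @param object An `abexp_track_mapping`.
#' @param ... Unused.
#' @export
predict.abexp_track_mapping <- function(object, u, ...) {
  u <- as.matrix(u)
  ridge_predict(object$fit, log10(1 + u))
}

#' Variant effect on the canonical transcript
#'
#' Difference of predicted log10 expression between alternative and reference
#' sequence, expressed on a doublings scale by dividing by log10(2): a score
#' of 1 corresponds to a predicted doubling.
#'
#' @param y_hat_alt,y_hat_ref Predicted expression (log10 scale) for the
#'   alternative and reference sequence.
#' @return Numeric effect score.
#' @export
score_canonical <- function(y_hat_alt, y_hat_ref) {
  (y_hat_alt - y_hat_ref) / log10(2)
}

#' Isoform-proportion-weighted variant effect
#'
#' log2 ratio of proportion-weighted predicted expression (on the TPM scale,
#' `10^y_hat`) of alternative over reference across the gene's isoforms near
#' the variant. With a single isoform of proportion 1 this equals
#' [score_canonical()] exactly.
#'
#' @param y_hat_alt,y_hat_ref Predicted expression per isoform (parallel
#'   vectors).
#' @param proportions Isoform proportions (same length).
#' @return Numeric effect score.
#' @export
score_weighted <- function(y_hat_alt, y_hat_ref, proportions) {
  if (length(y_hat_alt) != length(y_hat_ref) ||
      length(y_hat_alt) != length(proportions))
    stop("inputs must have equal length")
  den <- sum(proportions * 10^y_hat_ref)
  if (den == 0) stop("zero proportion-weighted reference expression")
  log2(sum(proportions * 10^y_hat_alt) / den)
}

#' Signed maximum-absolute aggregation of variant effect scores
#'
#' Collapses the per-variant effect scores of a gene/individual/tissue into
#' the score of maximum absolute value, keeping its sign. Ties on |score| are
#' broken by the first occurrence after a deterministic sort of the scores.
#'
#' @param scores Numeric vector of per-variant scores (non-empty).
#' @return Scalar aggregated score.
#' @export
#' @examples
#' aggregate_variant_scores(c(-2, 1))  # -2
aggregate_variant_scores <- function(scores) {
  if (length(scores) == 0L) stop("no scores to aggregate")
  s <- sort(scores)
  s[which.max(abs(s))]
}

#' Restrict variant effect scores to a TSS applicability window
#'
#' Promoter-focused sequence models are only considered predictive close to
#' the transcription start site; variants outside `[window[1], window[2]]`
#' (bp relative to the TSS, strand-aware sign) get `NA`.
#'
#' @param scores Numeric scores.
#' @param tss_distance Signed distance to TSS per score.
#' @param window Length-2 numeric window (default `c(-50, 200)`).
#' @return Scores with out-of-window entries set to `NA`.
#' @export
apply_tss_window <- function(scores, tss_distance, window = c(-50, 200)) {
  out <- scores
  out[tss_distance < window[1] | tss_distance > window[2]] <- NA_real_
  out
}
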