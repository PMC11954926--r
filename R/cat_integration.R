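#' Target tissues excluded for a clinically accessible tissue (CAT)
#'
#' When RNA-seq from a CAT is folded into the prediction, the CAT itself and
#' tissues highly related to it are excluded from the predicted targets:
#' fibroblasts exclude both skin tissues and cultured fibroblasts; whole
#' blood excludes whole blood and EBV-transformed lymphocytes.
#'
#' @param cat One of `"fibroblasts"`, `"whole_blood"`.
#' @return Character vector of excluded target tissues.
#' @export
cat_tissue_exclusions <- function(cat) {
  switch(cat,
    fibroblasts = c("Skin - Not Sun Exposed (Suprapubic)",
                    "Skin - Sun Exposed (Lower leg)",
                    "Cells - Cultured fibroblasts"),
    whole_blood = c("Whole Blood", "Cells - EBV-transformed lymphocytes"),
    stop("unknown CAT: ", cat))
}

#' Build the 6-predictor feature vectors for CAT integration
#'
#' Per (gene, individual, target tissue): a binary flag for whether the gene
#' is expressed in the CAT (i.e. present in the CAT outlier table), the CAT
#' z-score (0 when not expressed), the DNA-based prediction for the target
#' tissue, and the three pairwise interaction terms.
#'
#' @param abexp_preds Table with `gene_id`, `individual_id`, `tissue`,
#'   `z_pred`.
#' @param cat_z Table with `gene_id`, `individual_id`, `cat_z` for genes
#'   expressed (assessable) in the CAT.
#' @return `data.table` with columns `expressed`, `cat_z`, `abexp`,
#'   `expressed_cat_z`, `expressed_abexp`, `cat_z_abexp` plus keys. Rows of
#'   `abexp_preds` without a prediction are skipped (count reported via a
#'   message).
#' @export
build_cat_features <- function(abexp_preds, cat_z) {
  ap <- as.data.table(abexp_preds)
  n_missing <- sum(is.na(ap$z_pred))
  if (n_missing > 0) {
    message(n_missing, " rows without a DNA-based prediction skipped")
    ap <- ap[!is.na(z_pred)]
  }
  cz <- as.data.table(cat_z)[, .(gene_id, individual_id, cat_z)]
  out <- merge(ap, cz, by = c("gene_id", "individual_id"), all.x = TRUE)
  out[, expressed := as.integer(!is.na(cat_z))]
  out[is.na(cat_z), cat_z := 0]
  setnames(out, "z_pred", "abexp")
  out[, `:=`(expressed_cat_z = expressed * cat_z,
             expressed_abexp = expressed * abexp,
             cat_z_abexp = cat_z * abexp)]
  out[]
}

.cat_predictors <- c("expressed", "cat_z", "abexp",
                     "expressed_cat_z", "expressed_abexp", "cat_z_abexp")

#' Fit the CAT-integration logistic model with grouped cross-validation
#'
#' A plain maximum-likelihood logistic regression (intercept + the six
#' predictors of [build_cat_features()]) predicting underexpression-outlier
#' status, fit per fold on the other folds' individuals; out-of-fold
#' probabilities are returned for held-out individuals only. On complete
#' separation (non-converged or exploding coefficients) the fit falls back to
#' a small ridge penalty via iterated reweighted least squares, with a
#' warning.
#'
#' @param features Table from [build_cat_features()].
#' @param labels Binary underexpression-outlier status per row.
#' @param folds Named fold assignment from [make_cv_folds()].
#' @param ridge Penalty used only by the separation fallback (default 1e-3).
#' @return Object of class `abexp_cat_model` with per-fold coefficient
#'   vectors and `oof` probabilities.
#' @export
fit_cat_model <- function(features, labels, folds, ridge = 1e-3) {
  dt <- as.data.table(features)
  y <- as.integer(labels)
  fold_of_row <- unname(folds[dt$individual_id])
  fold_ids <- sort(unique(unname(folds)))
  X <- as.matrix(dt[, .cat_predictors, with = FALSE])
  coefs <- list()
  oof <- rep(NA_real_, nrow(dt))
  for (k in fold_ids) {
    tr <- fold_of_row != k
    b <- .fit_logistic(X[tr, , drop = FALSE], y[tr], ridge = ridge)
    coefs[[as.character(k)]] <- b
    oof[!tr] <- .plogis_lin(X[!tr, , drop = FALSE], b)
  }
  out <- dt[, .(gene_id, individual_id, tissue)]
  out[, p_outlier := oof]
  structure(list(coefs = coefs, predictors = .cat_predictors, oof = out),
            class = "abexp_cat_model")
}

.fit_logistic <- function(X, y, ridge = 1e-3) {
  df <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  if (sep || !fit$converged || any(!is.finite(b)) ||
      max(abs(b), na.rm = TRUE) > 1e3) {
    warning("possible complete separation; refitting with a small ridge penalty")
    b <- .ridge_logistic(cbind(1, X), y, lambda = ridge)
  }
  b[is.na(b)] <- 0
  names(b) <- c("(Intercept)", colnames(X))
  b
}

# Newton iterations for L2-penalised logistic log-likelihood
# (intercept unpenalised); X1 includes the intercept column.
.ridge_logistic <- function(X1, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  p <- ncol(X1)
  b <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% b
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H, grad)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

.plogis_lin <- function(X, b) {
  eta <- drop(cbind(1, X) %*% b)
  p <- 1 / (1 + exp(-eta))
  # keep probabilities strictly inside (0, 1) even for extreme linear predictors
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Predict outlier probabilities with a fitted CAT model
#'
#' Deployment prediction averages the per-fold coefficient vectors' linear
#' predictors before the inverse-logit.
#'
#' @param object `abexp_cat_model`.
#' @param features Table from [build_cat_features()].
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.abexp_cat_model <- function(object, features, ...) {
  dt <- as.data.table(features)
  X <- as.matrix(dt[, object$predictors, with = FALSE])
  bbar <- Reduce(`+`, object$coefs) / length(object$coefs)
  .plogis_lin(X, bbar)
}
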