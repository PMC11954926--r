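#' Default gradient-boosted-tree configuration
#'
#' Hyperparameters of the z-score regressor: 100 leaf-wise-grown trees with at
#' most 31 leaves, learning rate 0.1, minimum child weight 0.001, no
#' subsampling and no regularisation, trained with 6 individual-grouped
#' cross-validation folds.
#'
#' @param n_folds Number of cross-validation folds (default 6).
#' @param seed Integer seed for fold shuffling and tree training.
#' @param nrounds,learning_rate,num_leaves,min_child_weight,subsample,reg_alpha,reg_lambda
#'   Tree-ensemble hyperparameters.
#' @return List of class `abexp_model_config`.
#' @export
abexp_config <- function(n_folds = 6, seed = 1L, nrounds = 100,
                         learning_rate = 0.1, num_leaves = 31,
                         min_child_weight = 0.001, subsample = 1,
                         reg_alpha = 0, reg_lambda = 0) {
  stopifnot(n_folds >= 2, nrounds >= 1, learning_rate > 0, num_leaves >= 2,
            subsample > 0, subsample <= 1, reg_alpha >= 0, reg_lambda >= 0)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 nrounds = nrounds, learning_rate = learning_rate,
                 num_leaves = num_leaves, min_child_weight = min_child_weight,
                 subsample = subsample, reg_alpha = reg_alpha,
                 reg_lambda = reg_lambda),
            class = "abexp_model_config")
}

#' Assign individuals to balanced cross-validation folds
#'
#' Individuals are grouped (never split) across folds so that no individual
#' contributes to both the training and held-out side of any fold. Balance is
#' achieved greedily: individuals are sorted by descending outlier count
#' (ties shuffled with the seed) and each is assigned to the fold currently
#' holding the fewest outliers, ties broken by fold size then fold index.
#'
#' @param individuals Character vector of individual ids.
#' @param outlier_counts Non-negative outlier count per individual (same
#'   order); default all zero (pure size balancing).
#' @param n_folds Number of folds (default 6).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Named integer vector individual -> fold index in `[0, n_folds)`.
#' @export
make_cv_folds <- function(individuals, outlier_counts = NULL, n_folds = 6,
                          seed = 1L) {
  n <- length(individuals)
  if (anyDuplicated(individuals)) stop("duplicated individual ids")
  if (n < n_folds) stop("fewer individuals than folds")
  if (is.null(outlier_counts)) outlier_counts <- rep(0, n)
  if (any(outlier_counts < 0)) stop("outlier counts must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- order(-outlier_counts, sample.int(n))
  fold_out <- numeric(n_folds)
  fold_size <- integer(n_folds)
  assign <- integer(n)
  for (i in ord) {
    k <- order(fold_out, fold_size, seq_len(n_folds))[1]
    assign[i] <- k - 1L
    fold_out[k] <- fold_out[k] + outlier_counts[i]
    fold_size[k] <- fold_size[k] + 1L
  }
  setNames(assign, individuals)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.xgb_params <- function(config) {
  list(objective = "reg:squarederror",
       tree_method = "hist", grow_policy = "lossguide",
       max_depth = 0, max_leaves = config$num_leaves,
       eta = config$learning_rate,
       min_child_weight = config$min_child_weight,
       subsample = config$subsample,
       alpha = config$reg_alpha, lambda = config$reg_lambda,
       nthread = 1)
}

#' Train the z-score regressor with individual-grouped cross-validation
#'
#' For each fold a gradient-boosted-tree regressor is trained on all other
#' folds' rows and predictions are emitted only for the held-out fold's
#' individuals, so no out-of-fold prediction ever uses a model that saw that
#' individual. The regression target is the expression z-score (negative =
#' underexpression); ranking rows by ascending prediction ranks candidate
#' underexpression outliers first.
#'
#' @param features Feature table from [aggregate_gene_features()] including
#'   `individual_id` (feature columns found via [feature_columns()]).
#' @param targets Numeric z-score per row of `features`.
#' @param folds Named fold assignment from [make_cv_folds()].
#' @param config [abexp_config()] object.
#' @return Object of class `abexp_model` with per-fold boosters, the feature
#'   schema, config, and `oof` (out-of-fold predictions joined to the input
#'   rows).
#' @export
train_abexp <- function(features, targets, folds, config = abexp_config()) {
  dt <- as.data.table(features)
  if (nrow(dt) != length(targets)) stop("features and targets differ in length")
  miss_ind <- setdiff(unique(dt$individual_id), names(folds))
  if (length(miss_ind)) stop("individuals without fold assignment: ",
                             paste(head(miss_ind), collapse = ", "))
  fcols <- feature_columns(dt)
  if (length(fcols) == 0L) stop("no feature columns found")
  X <- as.matrix(dt[, ..fcols])
  storage.mode(X) <- "double"
  fold_of_row <- unname(folds[dt$individual_id])
  fold_ids <- sort(unique(unname(folds)))
  boosters <- vector("list", length(fold_ids))
  names(boosters) <- as.character(fold_ids)
  oof <- rep(NA_real_, nrow(dt))
  for (k in fold_ids) {
    tr <- fold_of_row != k
    te <- !tr
    if (sum(targets[te] < 0, na.rm = TRUE) == 0L)
      warning("fold ", k, " holds no negative-z rows; fold metrics may be undefined")
    old <- .Random.seed_save(); set.seed(config$seed + k)
    bst <- xgboost::xgb.train(
      params = .xgb_params(config),
      data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = targets[tr]),
      nrounds = config$nrounds, verbose = 0)
    .Random.seed_restore(old)
    boosters[[as.character(k)]] <- bst
    oof[te] <- predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
  }
  out <- dt[, .(gene_id, individual_id, tissue)]
  out[, z_pred := oof]
  structure(list(boosters = boosters, feature_names = fcols,
                 config = config, folds = folds, oof = out),
            class = "abexp_model")
}

#' Predict z-scores for new feature rows
#'
#' Applies the trained model; with several per-fold boosters the deployment
#' prediction is their mean. The feature schema must match the training
#' schema exactly.
#'
#' @param object `abexp_model`.
#' @param features Feature table with the training feature columns.
#' @param ... Unused.
#' @return `data.table` with `gene_id`, `individual_id`, `tissue`, `z_pred`
#'   and `confidence` (see [classify_abexp()]).
#' @export
predict.abexp_model <- function(object, features, ...) {
  dt <- as.data.table(features)
  missing_f <- setdiff(object$feature_names, names(dt))
  extra_f <- setdiff(grep("^feat_", names(dt), value = TRUE),
                     object$feature_names)
  if (length(missing_f) || length(extra_f))
    stop("feature schema mismatch; missing: [",
         paste(missing_f, collapse = ", "), "] extra: [",
         paste(extra_f, collapse = ", "), "]")
  X <- as.matrix(dt[, object$feature_names, with = FALSE])
  storage.mode(X) <- "double"
  dm <- xgboost::xgb.DMatrix(X)
  preds <- rowMeans(vapply(object$boosters, function(b) predict(b, dm),
                           numeric(nrow(X))))
  keys <- intersect(c("gene_id", "individual_id", "tissue"), names(dt))
  out <- dt[, keys, with = FALSE]
  out[, z_pred := preds]
  out[, confidence := classify_abexp(z_pred)]
  out[]
}

#' Confidence class of a predicted z-score
#'
#' High confidence below the high cutoff (default -3.84, about 50% precision
#' on the original benchmark), low confidence between the cutoffs (default
#' low cutoff -1.64, about 20% precision), otherwise none. Boundaries are
#' strict `<`.
#'
#' @param z_pred Numeric predictions.
#' @param cutoff_high,cutoff_low Cutoffs with `cutoff_high < cutoff_low`.
#' @return Character vector in `{"high", "low", "none"}`.
#' @export
#' @examples
#' classify_abexp(c(-4, -2, -1.64, 0))  # high, low, none, none
classify_abexp <- function(z_pred, cutoff_high = -3.84, cutoff_low = -1.64) {
  if (!(cutoff_high < cutoff_low)) stop("cutoff_high must be below cutoff_low")
  ifelse(z_pred < cutoff_high, "high",
         ifelse(z_pred < cutoff_low, "low", "none"))
}

#' @export
print.abexp_model <- function(x, ...) {
  cat("abexp z-score model:", length(x$boosters), "fold boosters,",
      length(x$feature_names), "features\n")
  invisible(x)
}
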