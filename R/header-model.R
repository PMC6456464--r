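# Header-based probability models: gradient boosting (primary), elastic-net
# logistic regression, and the single-field ViewModifierCode baseline, with
# stratified fivefold cross-validated hyperparameter search selected on
# auROC.

#' Default gradient-boosting hyperparameter grid
#'
#' @return data frame over tree depth \{2, 3, 4\}, learning rate
#'   \{0.05, 0.1\} and boosting rounds \{100, 300\}.
#' @export
default_gbm_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1),
              nrounds = c(100L, 300L))
}

#' Default elastic-net mixing grid
#'
#' @return data frame with the L1 ratio `alpha` in \{0, 0.25, 0.5, 0.75,
#'   1\}; the overall penalty strength is searched internally along the
#'   glmnet lambda path.
#' @export
default_enet_grid <- function() {
  data.frame(alpha = c(0, 0.25, 0.5, 0.75, 1))
}

# stratified fold assignment: within each class, cycle fold labels over a
# shuffled order
.stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    id[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

.xgb_fit <- function(X, y, max_depth, eta, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, tree_method = "exact", nthread = 1,
                  subsample = 1, colsample_bytree = 1),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

.xgb_predict <- function(fit, X) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Train a header-based classifier
#'
#' Runs a stratified `folds`-fold cross-validated grid search within the
#' training rows, selects the grid point with the highest mean validation
#' auROC (ties broken by grid order), and refits on all rows at that
#' setting. Deterministic given the seed.
#'
#' @param X a `feature_matrix` (or plain numeric matrix with column names).
#' @param y binary labels, 1 = special view.
#' @param kind `"gbm"` (gradient boosting, default), `"elastic_net"`, or
#'   `"single_field"` (delegates to [single_field_baseline()]; requires
#'   `records`).
#' @param grid hyperparameter grid data frame; defaults per kind.
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param records header records, only for `kind = "single_field"`.
#' @return a `header_model` with elements `kind`, `fit`, `feature_names`,
#'   `cv_results` (grid with mean CV auROC), `feature_importance` (for gbm:
#'   relative influence summing to 100).
#' @export
train_header_model <- function(X, y, kind = c("gbm", "elastic_net", "single_field"),
                               grid = NULL, folds = 5L, seed = 0L,
                               records = NULL) {
  kind <- match.arg(kind)
  if (kind == "single_field") {
    if (is.null(records)) stop("single_field kind requires records")
    return(single_field_baseline(records, y))
  }
  y <- .check_binary(y)
  Xm <- unclass(X)
  stopifnot(nrow(Xm) == length(y))
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present in y")
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > min(counts)) {
    stop("folds (", folds, ") exceeds the minority-class count (",
         min(counts), ")")
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  fold_id <- .stratified_folds(y, folds)

  if (kind == "gbm") {
    if (is.null(grid)) grid <- default_gbm_grid()
    cv_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      aucs <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- .xgb_fit(Xm[tr, , drop = FALSE], y[tr], grid$max_depth[g],
                        grid$eta[g], grid$nrounds[g])
        auroc(.xgb_predict(fit, Xm[!tr, , drop = FALSE]), y[!tr])
      }, 0)
      cv_auc[g] <- mean(aucs)
    }
    best <- which.max(cv_auc) # ties: first occurrence in grid order
    fit <- .xgb_fit(Xm, y, grid$max_depth[best], grid$eta[best],
                    grid$nrounds[best])
    imp <- xgboost::xgb.importance(model = fit)
    importance <- stats::setNames(rep(0, ncol(Xm)), colnames(Xm))
    importance[imp$Feature] <- imp$Gain * 100
    model <- list(kind = "gbm", fit = fit,
                  feature_names = colnames(Xm),
                  cv_results = cbind(grid, mean_cv_auroc = cv_auc),
                  best_params = grid[best, , drop = FALSE],
                  feature_importance = importance, seed = seed)
  } else {
    if (is.null(grid)) grid <- default_enet_grid()
    cv_fits <- lapply(grid$alpha, function(a) {
      glmnet::cv.glmnet(Xm, y, family = "binomial", alpha = a,
                        foldid = fold_id, type.measure = "auc")
    })
    cv_auc <- vapply(cv_fits, function(f) max(f$cvm), 0)
    best <- which.max(cv_auc)
    fit <- cv_fits[[best]]
    coefs <- abs(as.numeric(stats::coef(fit, s = "lambda.min"))[-1])
    importance <- stats::setNames(coefs, colnames(Xm))
    model <- list(kind = "elastic_net", fit = fit,
                  feature_names = colnames(Xm),
                  cv_results = cbind(grid, mean_cv_auroc = cv_auc),
                  best_params = data.frame(alpha = grid$alpha[best],
                                           lambda = fit$lambda.min),
                  feature_importance = importance, seed = seed)
  }
  structure(model, class = "header_model")
}

#' @export
print.header_model <- function(x, ...) {
  cat("<header_model> kind =", x$kind, "\n")
  if (!is.null(x$best_params)) {
    cat("  selected:", paste(names(x$best_params), unlist(x$best_params),
                             sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$feature_importance)) {
    top <- sort(x$feature_importance, decreasing = TRUE)[1:min(5, length(x$feature_importance))]
    cat("  top features:", paste(names(top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score with a header model
#'
#' Columns of `X` are aligned to the model's feature names; a mismatch in
#' the column set is an error that lists the missing and extra columns.
#' For the single-field baseline pass `records` (or a character vector of
#' field values) instead of a feature matrix.
#'
#' @param model a `header_model`.
#' @param X feature matrix, or for `kind = "single_field"` a list of
#'   `header_record` / character vector of field values.
#' @return probability of the special-view class per row, in \[0, 1\].
#' @export
predict_header <- function(model, X) {
  stopifnot(inherits(model, "header_model"))
  if (model$kind == "single_field") return(.predict_single_field(model, X))
  Xm <- unclass(X)
  missing <- setdiff(model$feature_names, colnames(Xm))
  extra <- setdiff(colnames(Xm), model$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature columns do not match the model: missing [",
         paste(missing, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]")
  }
  Xm <- Xm[, model$feature_names, drop = FALSE]
  if (model$kind == "gbm") {
    .xgb_predict(model$fit, Xm)
  } else {
    as.numeric(stats::predict(model$fit, newx = Xm, s = "lambda.min",
                              type = "response"))
  }
}

#' Single-field baseline on ViewModifierCode
#'
#' Scores each category of one header field by its Laplace-smoothed
#' training positive rate `(n_pos + alpha) / (n + 2 alpha)`. Records with
#' the field absent are scored by the absent-group's positive rate;
#' categories unseen in training fall back to the global positive rate.
#'
#' @param records list of `header_record` (training split).
#' @param y binary labels.
#' @param field header field to score on (default `"ViewModifierCode"`).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return a `header_model` of kind `"single_field"`.
#' @export
single_field_baseline <- function(records, y, field = "ViewModifierCode",
                                  alpha = 1) {
  y <- .check_binary(y)
  stopifnot(length(records) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  values <- vapply(records, function(r) {
    v <- r$tags[[field]]
    if (is.null(v)) NA_character_ else paste(as.character(v), collapse = "\\")
  }, "")
  rate <- function(sel) {
    (sum(y[sel] == 1L) + alpha) / (sum(sel) + 2 * alpha)
  }
  cats <- sort(unique(values[!is.na(values)]))
  scores <- vapply(cats, function(cat) rate(!is.na(values) & values == cat), 0)
  structure(list(
    kind = "single_field", field = field, alpha = alpha,
    category_scores = stats::setNames(scores, cats),
    absent_score = if (any(is.na(values))) rate(is.na(values)) else
      mean(y == 1L),
    global_score = mean(y == 1L),
    feature_names = field, cv_results = NULL, feature_importance = NULL,
    fit = NULL
  ), class = "header_model")
}

.predict_single_field <- function(model, X) {
  values <- if (is.character(X)) {
    X
  } else {
    vapply(X, function(r) {
      v <- r$tags[[model$field]]
      if (is.null(v)) NA_character_ else paste(as.character(v), collapse = "\\")
    }, "")
  }
  vapply(values, function(v) {
    if (is.na(v)) {
      return(model$absent_score)
    }
    i <- match(v, names(model$category_scores)) # "" is a valid category
    if (is.na(i)) model$global_score else unname(model$category_scores[i])
  }, 0, USE.NAMES = FALSE)
}
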