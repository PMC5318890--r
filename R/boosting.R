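#' Gradient-boosting configuration
#'
#' Defaults follow the study's reported settings: Gaussian loss, 1500
#' iterations, interaction depth 5 (five splits per best-first-grown tree),
#' learning rate 0.005, 5-fold cross-validation. Bag fraction 0.5 and
#' minimum node size 10 are the conventional defaults of this model family;
#' both are configurable and echoed in model metadata.
#'
#' All randomness (fold assignment, bagging) flows from `seed`: the fold
#' partition uses `seed`, the k fold fits use `seed + 1 .. seed + k`, and
#' the final all-data fit uses `seed + k + 1`.
#'
#' @param n_trees number of boosting iterations.
#' @param interaction_depth splits per tree (>= 1).
#' @param learning_rate shrinkage in (0, 1].
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param bag_fraction row subsample fraction per iteration, in (0, 1].
#' @param min_node_size minimum observations per terminal node.
#' @param seed master integer seed.
#' @return A `gbm_config` object.
#' @export
gbm_config <- function(n_trees = 1500L, interaction_depth = 5L,
                       learning_rate = 0.005, cv_folds = 5L,
                       bag_fraction = 0.5, min_node_size = 10L,
                       seed = 1L) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]")
  if (interaction_depth < 1) stop("interaction_depth must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must lie in (0, 1]")
  if (n_trees < 1 || min_node_size < 1) stop("invalid n_trees/min_node_size")
  structure(list(n_trees = as.integer(n_trees),
                 interaction_depth = as.integer(interaction_depth),
                 learning_rate = learning_rate,
                 cv_folds = as.integer(cv_folds),
                 bag_fraction = bag_fraction,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "gbm_config")
}

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X)) stop("missing predictor values not allowed")
  X
}

#' Fit one regression tree to residuals
#'
#' Best-first growth: at each step the frontier leaf whose best admissible
#' split most reduces the total within-node squared error is split, until
#' `depth` splits are placed or no split reduces error while respecting
#' `min_node`. Split candidates are midpoints between consecutive distinct
#' sorted values; improvement ties break toward the lowest variable index,
#' then the lowest threshold. Constant residuals give a single-leaf tree
#' predicting their mean.
#'
#' @param X numeric predictor matrix.
#' @param r residual (response) vector.
#' @param depth maximum number of splits.
#' @param min_node minimum rows per child node.
#' @param rows optional integer subset of rows to grow on (the bag);
#'   default all rows.
#' @return A `regression_tree`: data.frame with one row per node (`var`,
#'   `threshold`, `left`, `right`, `pred`, `improvement`; `var` is `NA` at
#'   leaves).
#' @export
fit_tree <- function(X, r, depth = 5L, min_node = 10L, rows = NULL) {
  X <- as_predictor_matrix(X)
  if (is.null(rows)) rows <- seq_len(nrow(X))
  tree <- cpp_fit_tree(X, as.numeric(r), as.integer(rows) - 1L,
                       as.integer(depth), as.integer(min_node))
  structure(as.data.frame(tree), class = c("regression_tree", "data.frame"))
}

#' @rdname fit_tree
#' @param tree a `regression_tree`.
#' @export
predict_tree <- function(tree, X) {
  cpp_predict_tree(as.list(tree), as_predictor_matrix(X))
}

boost_core <- function(X, y, config, seed, X_eval = NULL, y_eval = NULL) {
  n <- nrow(X)
  set.seed(as.integer(seed))
  init <- mean(y)
  f <- rep(init, n)
  trees <- vector("list", config$n_trees)
  train_error <- numeric(config$n_trees)
  eval_error <- if (!is.null(X_eval)) numeric(config$n_trees) else NULL
  if (!is.null(X_eval)) fe <- rep(init, nrow(X_eval))
  bag_size <- max(round(config$bag_fraction * n), 2 * config$min_node_size)
  bag_size <- min(bag_size, n)
  for (m in seq_len(config$n_trees)) {
    bag <- if (config$bag_fraction < 1) sort(sample.int(n, bag_size))
           else seq_len(n)
    tree <- cpp_fit_tree(X, y - f, bag - 1L, config$interaction_depth,
                         config$min_node_size)
    f <- f + config$learning_rate * cpp_predict_tree(tree, X)
    train_error[m] <- mean((y - f)^2)
    if (!is.null(X_eval)) {
      fe <- fe + config$learning_rate * cpp_predict_tree(tree, X_eval)
      eval_error[m] <- mean((y_eval - fe)^2)
    }
    trees[[m]] <- tree
  }
  list(init = init, trees = trees, train_error = train_error,
       eval_error = eval_error)
}

#' Fit a gradient-boosted regression-tree model (Gaussian loss)
#'
#' Stagewise additive modelling: the fit starts at the training-response
#' mean; each iteration fits a regression tree ([fit_tree()]) to the current
#' residuals on a seeded `bag_fraction` row subsample and adds
#' `learning_rate` times its predictions. Cross-validation re-runs the same
#' procedure on seeded random fold partitions; `best_iteration` minimises
#' the fold-averaged held-out squared error, and the returned model is the
#' all-data fit (full error curves are retained, predictions default to
#' truncation at `best_iteration`).
#'
#' @param X predictor matrix or data.frame (numeric, complete).
#' @param y numeric response.
#' @param config a [gbm_config()].
#' @return A `gbm_model`: list with `init`, `trees`, `config`, `var_names`,
#'   `best_iteration`, `train_error`, `cv_error`, `X` (training predictors,
#'   kept for partial dependence).
#' @export
fit_gbm <- function(X, y, config = gbm_config()) {
  stopifnot(inherits(config, "gbm_config"))
  X <- as_predictor_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (anyNA(y)) stop("missing response values not allowed")
  if (n < config$cv_folds) stop("need at least cv_folds rows")

  set.seed(config$seed)
  folds <- sample(rep_len(seq_len(config$cv_folds), n))
  cv_mat <- matrix(NA_real_, config$n_trees, config$cv_folds)
  for (k in seq_len(config$cv_folds)) {
    tr <- folds != k
    fit <- boost_core(X[tr, , drop = FALSE], y[tr], config,
                      seed = config$seed + k,
                      X_eval = X[!tr, , drop = FALSE], y_eval = y[!tr])
    cv_mat[, k] <- fit$eval_error
  }
  cv_error <- rowMeans(cv_mat)
  best_iteration <- which.min(cv_error)
  final <- boost_core(X, y, config, seed = config$seed + config$cv_folds + 1)
  structure(list(init = final$init, trees = final$trees, config = config,
                 var_names = colnames(X),
                 best_iteration = best_iteration,
                 train_error = final$train_error, cv_error = cv_error,
                 X = X),
            class = "gbm_model")
}

#' @export
print.gbm_model <- function(x, ...) {
  cat(sprintf(
    "Gradient-boosted regression trees (Gaussian loss)\n  %d predictors, %d training rows\n  %d trees, depth %d, learning rate %g, bag fraction %g\n  CV-selected iteration: %d (CV MSE %.4g)\n",
    length(x$var_names), nrow(x$X), x$config$n_trees,
    x$config$interaction_depth, x$config$learning_rate,
    x$config$bag_fraction, x$best_iteration, x$cv_error[x$best_iteration]))
  invisible(x)
}

#' Predict from a boosted model
#'
#' @param object a `gbm_model`.
#' @param newdata predictor matrix/data.frame with the model's columns.
#' @param n_trees number of trees to use (default the CV-selected
#'   `best_iteration`).
#' @param ... unused.
#' @export
predict.gbm_model <- function(object, newdata, n_trees = NULL, ...) {
  if (is.null(n_trees)) n_trees <- object$best_iteration
  stopifnot(n_trees >= 0, n_trees <= length(object$trees))
  newdata <- if (is.data.frame(newdata))
    as_predictor_matrix(newdata[, object$var_names, drop = FALSE])
  else as_predictor_matrix(newdata)
  cpp_predict_ensemble(object$trees, newdata, object$init,
                       object$config$learning_rate, as.integer(n_trees))
}

#' Relative influence of each predictor
#'
#' Per predictor, the sum of squared-error improvements over all splits on
#' that predictor in trees `1..n_trees`, normalised to total 100 (percent).
#' A model with no splits returns an all-zero table flagged with attribute
#' `no_splits`.
#'
#' @param model a `gbm_model`.
#' @param n_trees trees to include (default `best_iteration`).
#' @return Named numeric vector (percent), one entry per predictor,
#'   decreasing.
#' @export
relative_influence <- function(model, n_trees = NULL) {
  stopifnot(inherits(model, "gbm_model"))
  if (is.null(n_trees)) n_trees <- model$best_iteration
  infl <- setNames(numeric(length(model$var_names)), model$var_names)
  for (tree in model$trees[seq_len(n_trees)]) {
    splits <- !is.na(tree$var)
    if (any(splits)) {
      add <- tapply(tree$improvement[splits], tree$var[splits], sum)
      idx <- as.integer(names(add))
      infl[idx] <- infl[idx] + add
    }
  }
  total <- sum(infl)
  if (total == 0) {
    warning("model contains no splits; influence undefined (all zero)")
    attr(infl, "no_splits") <- TRUE
    return(infl)
  }
  sort(100 * infl / total, decreasing = TRUE)
}

default_grid <- function(x, length_out) {
  seq(min(x), max(x), length.out = length_out)
}

#' Partial dependence of the model on one or two predictors
#'
#' The empirical partial-dependence function: for each grid point the named
#' predictor column(s) of the training data are overwritten by the grid
#' value and the model predictions averaged over all rows (all other
#' covariates kept at their observed values). This direct data-average is
#' the definition itself, computed exactly.
#'
#' @param model a `gbm_model`.
#' @param vars one or two predictor names.
#' @param grid optional grid: numeric vector (one variable) or list of two
#'   numeric vectors; defaults to 25 (one variable) or 13-by-13 (two)
#'   equally spaced points over the observed range. Grid values must lie
#'   within the observed predictor range.
#' @param n_trees trees to use (default `best_iteration`).
#' @return data.frame with the grid column(s) and `yhat`; class
#'   `pdp_result`.
#' @export
partial_dependence <- function(model, vars, grid = NULL, n_trees = NULL) {
  stopifnot(inherits(model, "gbm_model"),
            length(vars) %in% c(1L, 2L))
  missing_vars <- setdiff(vars, model$var_names)
  if (length(missing_vars))
    stop("variable(s) not in model: ", paste(missing_vars, collapse = ", "))
  if (is.null(n_trees)) n_trees <- model$best_iteration
  X <- model$X
  if (length(vars) == 1L) {
    g <- if (is.null(grid)) default_grid(X[, vars], 25L) else sort(unique(grid))
    check_grid_range(g, X[, vars], vars)
    grid_df <- data.frame(g)
    names(grid_df) <- vars
  } else {
    if (is.null(grid)) grid <- lapply(vars, function(v) default_grid(X[, v], 13L))
    stopifnot(is.list(grid), length(grid) == 2L)
    for (i in 1:2) check_grid_range(grid[[i]], X[, vars[i]], vars[i])
    grid_df <- expand.grid(grid[[1]], grid[[2]], KEEP.OUT.ATTRS = FALSE)
    names(grid_df) <- vars
  }
  yhat <- vapply(seq_len(nrow(grid_df)), function(i) {
    Xi <- X
    for (v in vars) Xi[, v] <- grid_df[[v]][i]
    mean(predict(model, Xi, n_trees = n_trees))
  }, numeric(1))
  out <- cbind(grid_df, yhat = yhat)
  class(out) <- c("pdp_result", "data.frame")
  out
}

check_grid_range <- function(g, x, name) {
  if (any(g < min(x)) || any(g > max(x)))
    stop("grid for '", name, "' outside the observed predictor range")
  invisible(g)
}

#' Serialize a boosted model to JSON
#'
#' Writes init, configuration, best iteration and per-tree node lists.
#'
#' @param model a `gbm_model`.
#' @param path output file.
#' @param n_trees trees to write (default `best_iteration`).
#' @export
write_gbm_json <- function(model, path, n_trees = NULL) {
  if (is.null(n_trees)) n_trees <- model$best_iteration
  jsonlite::write_json(
    list(init = model$init, config = unclass(model$config),
         var_names = model$var_names, best_iteration = model$best_iteration,
         trees = lapply(model$trees[seq_len(n_trees)], as.data.frame)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
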