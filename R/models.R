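# Scoring-function regressors: multiple linear regression on the vina6
# features (model "mlr") and random forests on vina6 / vinaelem42
# (models "rf"), with per-seed OOB-driven mtry selection and 10-seed
# ensembles. The forest learner is ranger (500 regression trees by
# default, bootstrap resampling, mtry candidate features per split,
# OOB predictions, fully seedable).

.drop_id <- function(X) {
  if (is.data.frame(X) && "id" %in% names(X)) X[, setdiff(names(X), "id"), drop = FALSE]
  else X
}

.check_features <- function(model_names, X) {
  have <- colnames(X)
  missing <- setdiff(model_names, have)
  extra <- setdiff(have, model_names)
  if (length(missing) || length(extra)) {
    stop(structure(
      class = c("vf_feature_mismatch", "error", "condition"),
      list(message = paste0(
        "feature columns do not match the model",
        if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
        if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))),
        call = sys.call(-1))))
  }
  X[, model_names, drop = FALSE]
}

#' Fit a multiple linear regression scoring function
#'
#' Ordinary least squares of the affinity labels on the feature columns
#' (a recalibrated classical scoring function). Deterministic. When the
#' design is rank-deficient the fit falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param X feature table (matrix or data.frame; an `id` column is
#'   dropped automatically).
#' @param y numeric affinity vector (pKd/pKi), one per row of `X`.
#' @return an object of class `vf_mlr` with `intercept`, `coefficients`
#'   (aligned to `feature_names`) and `feature_names`.
#' @export
fit_mlr <- function(X, y) {
  X <- .drop_id(X)
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  n <- nrow(Xm); p <- ncol(Xm)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= p) stop("fit_mlr needs more observations than features", call. = FALSE)
  A <- cbind(`(Intercept)` = 1, Xm)
  qra <- qr(A)
  if (qra$rank < ncol(A)) {
    warning("rank-deficient design; fitting via pseudo-inverse", call. = FALSE)
    beta <- as.vector(MASS::ginv(A) %*% y)
  } else {
    beta <- qr.coef(qra, y)
  }
  structure(list(kind = "mlr",
                 intercept = unname(beta[1]),
                 coefficients = setNames(unname(beta[-1]), colnames(Xm)),
                 feature_names = colnames(Xm)),
            class = "vf_mlr")
}

#' @export
print.vf_mlr <- function(x, ...) {
  cat(sprintf("<vf_mlr: %d features>\n", length(x$coefficients)))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Random-forest training configuration
#'
#' The training protocol for the forest scoring functions: 500 trees, an
#' mtry grid spanning 1 to the number of features, 10 fixed seeds, and
#' lowest-mtry tie-breaking in the OOB selection.
#'
#' @param n_features number of feature columns (6 for `vina6`, 42 for
#'   `vinaelem42`); sets the default grid `1:n_features`.
#' @param n_trees trees per forest (default 500).
#' @param mtry_grid integer vector of candidate mtry values.
#' @param seeds integer vector of RNG seeds, one trained instance each
#'   (default `1:10`).
#' @return a list of class `rf_config`.
#' @export
rf_config <- function(n_features, n_trees = 500L,
                      mtry_grid = seq_len(n_features),
                      seeds = 1:10) {
  stopifnot(n_trees >= 1, length(mtry_grid) >= 1,
            all(mtry_grid >= 1), all(mtry_grid <= n_features))
  structure(list(n_features = as.integer(n_features),
                 n_trees = as.integer(n_trees),
                 mtry_grid = as.integer(sort(unique(mtry_grid))),
                 seeds = as.integer(seeds),
                 tie_break = "lowest-mtry"),
            class = "rf_config")
}

.fit_forest <- function(Xm, y, mtry, n_trees, seed) {
  ranger::ranger(x = Xm, y = y, num.trees = n_trees, mtry = mtry,
                 seed = seed, num.threads = 1, oob.error = TRUE,
                 respect.unordered.factors = FALSE)
}

.oob_rmse <- function(forest, y) {
  oob <- forest$predictions
  ok <- is.finite(oob)
  if (!all(ok)) {
    warning(sprintf("%d sample(s) had no out-of-bag predictions; excluded from OOB RMSE",
                    sum(!ok)), call. = FALSE)
  }
  sqrt(mean((y[ok] - oob[ok])^2))
}

#' Select mtry by out-of-bag error
#'
#' Fits one forest per candidate mtry value, all with the same seed,
#' computes each forest's RMSE on its out-of-bag predictions, and returns
#' the argmin (ties broken toward the smallest mtry). Samples that never
#' fall out of bag are excluded from the OOB RMSE with a warning.
#'
#' @param X feature table (an `id` column is dropped).
#' @param y numeric affinity vector.
#' @param seed integer RNG seed shared by all candidate forests.
#' @param config an [rf_config()].
#' @return a list with `selected_mtry`, `oob_rmse_by_mtry` (named numeric
#'   vector over the grid) and `forest` (the fitted forest at the
#'   selected mtry).
#' @export
select_mtry <- function(X, y, seed, config) {
  X <- .drop_id(X)
  Xm <- as.matrix(X); storage.mode(Xm) <- "double"
  if (nrow(Xm) < 20L) stop("select_mtry needs n >= 20", call. = FALSE)
  grid <- config$mtry_grid
  oob <- setNames(numeric(length(grid)), grid)
  best <- NULL; best_rmse <- Inf; best_mtry <- NA_integer_
  for (i in seq_along(grid)) {
    f <- .fit_forest(Xm, y, grid[i], config$n_trees, seed)
    oob[i] <- .oob_rmse(f, y)
    if (oob[i] < best_rmse) {  # strict '<' keeps the smallest mtry on ties
      best_rmse <- oob[i]; best <- f; best_mtry <- grid[i]
    }
  }
  list(selected_mtry = best_mtry, oob_rmse_by_mtry = oob, forest = best)
}

#' Fit one seeded random-forest scoring function
#'
#' Runs [select_mtry()] for the given seed and keeps the forest at the
#' selected mtry, recording the seed, the selection and the full OOB
#' curve.
#'
#' @inheritParams select_mtry
#' @return an object of class `vf_rf`.
#' @export
fit_rf <- function(X, y, seed, config) {
  X <- .drop_id(X)
  sel <- select_mtry(X, y, seed, config)
  structure(list(kind = "rf", seed = as.integer(seed),
                 selected_mtry = sel$selected_mtry,
                 oob_rmse_by_mtry = sel$oob_rmse_by_mtry,
                 forest = sel$forest,
                 feature_names = colnames(X)),
            class = "vf_rf")
}

#' @export
print.vf_rf <- function(x, ...) {
  cat(sprintf("<vf_rf: seed %d, mtry %d (OOB RMSE %.3f), %d features>\n",
              x$seed, x$selected_mtry,
              x$oob_rmse_by_mtry[as.character(x$selected_mtry)],
              length(x$feature_names)))
  invisible(x)
}

#' Fit the seeded random-forest ensemble
#'
#' One [fit_rf()] per configured seed (10 by default): each instance gets
#' its own OOB-driven mtry selection, giving slightly different trained
#' models whose median test performance summarizes the scoring function.
#'
#' @inheritParams select_mtry
#' @return an object of class `vf_rf_ensemble`: a list of `vf_rf` models.
#' @export
fit_rf_ensemble <- function(X, y, config) {
  X <- .drop_id(X)
  models <- lapply(config$seeds, function(s) fit_rf(X, y, s, config))
  structure(list(models = models, config = config), class = "vf_rf_ensemble")
}

#' @export
print.vf_rf_ensemble <- function(x, ...) {
  cat(sprintf("<vf_rf_ensemble: %d seeded models, mtry selections: %s>\n",
              length(x$models),
              paste(vapply(x$models, `[[`, integer(1), "selected_mtry"),
                    collapse = ", ")))
  invisible(x)
}

#' Predict affinities from a trained scoring function
#'
#' Deterministic given the trained model; prediction columns are matched
#' by feature name and a mismatch (missing or extra feature columns)
#' raises a typed error naming the offending columns.
#'
#' @param object a `vf_mlr`, `vf_rf` or `vf_rf_ensemble`.
#' @param newdata feature table (an `id` column is ignored).
#' @param ... unused.
#' @return numeric vector of predicted pKd (for an ensemble: a matrix
#'   with one column per seeded model).
#' @name predict-scoring
NULL

#' @rdname predict-scoring
#' @export
predict.vf_mlr <- function(object, newdata, ...) {
  X <- .check_features(object$feature_names, .drop_id(newdata))
  as.vector(object$intercept + as.matrix(X) %*% object$coefficients)
}

#' @rdname predict-scoring
#' @export
predict.vf_rf <- function(object, newdata, ...) {
  X <- .check_features(object$feature_names, .drop_id(newdata))
  predict(object$forest, data = as.data.frame(X), num.threads = 1)$predictions
}

#' @rdname predict-scoring
#' @export
predict.vf_rf_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$models, predict, numeric(nrow(.drop_id(newdata))),
                  newdata = newdata)
  colnames(preds) <- paste0("seed", vapply(object$models, `[[`, integer(1), "seed"))
  preds
}

#' Save / load a trained scoring function
#'
#' Serializes a trained model (kind, feature names, seed/mtry bookkeeping
#' and the forest or coefficient payload) with a format version tag.
#'
#' @param model a trained model object.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L))
    stop("unsupported model file version", call. = FALSE)
  obj$model
}
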