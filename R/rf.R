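#' Random-forest regressor
#'
#' A compact bagged-CART regressor used to re-rank candidate matches: 250
#' shallow trees (depth 5) fit on five features with squared-error splits,
#' the configuration the ranker is trained with. Deterministic given a
#' seed. Implemented in C++; no external learning library is required.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y numeric response in `[0, 1]` (Tanimoto labels).
#' @param n_estimators number of trees (default 250).
#' @param max_depth maximum tree depth (default 5).
#' @param min_samples_split minimum node size to attempt a split
#'   (default 2).
#' @param min_samples_leaf minimum samples per leaf (default 1).
#' @param seed integer seed controlling the bootstrap streams.
#' @param bootstrap draw a bootstrap sample per tree (default TRUE).
#' @return object of class `ms2_rf` (list of tree matrices plus the
#'   settings).
#' @export
rf_fit <- function(x, y, n_estimators = 250, max_depth = 5,
                   min_samples_split = 2, min_samples_leaf = 1,
                   seed = 1, bootstrap = TRUE) {
  x <- as.matrix(x)
  .assert(nrow(x) == length(y), "x and y sizes differ")
  .assert(all(is.finite(x)) && all(is.finite(y)),
          "features and labels must be finite")
  trees <- .rf_fit_cpp(x, as.numeric(y), as.integer(n_estimators),
                       as.integer(max_depth), as.integer(min_samples_split),
                       as.integer(min_samples_leaf), as.integer(seed),
                       isTRUE(bootstrap))
  structure(list(trees = trees, n_features = ncol(x),
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "ms2_rf")
}

#' Predict with a fitted random forest
#'
#' @param object an `ms2_rf` model.
#' @param newdata numeric feature matrix with `object$n_features` columns.
#' @param ... unused.
#' @return numeric vector of predictions (mean over trees).
#' @export
predict.ms2_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  .assert(ncol(newdata) == object$n_features,
          "feature count differs from training")
  .rf_predict_cpp(object$trees, newdata)
}

#' @exportS3Method base::print
print.ms2_rf <- function(x, ...) {
  cat(sprintf("<ms2_rf> %d trees, max depth %d, %d features\n",
              length(x$trees), x$max_depth, x$n_features))
  invisible(x)
}

# JSON-safe (de)serialisation of the tree list: each tree becomes a list
# of its five node columns (feature, threshold, left, right, value).
rf_to_list <- function(model) {
  list(n_features = model$n_features, n_estimators = model$n_estimators,
       max_depth = model$max_depth, seed = model$seed,
       trees = lapply(model$trees, function(m)
         list(feature = as.numeric(m[, 1]), threshold = as.numeric(m[, 2]),
              left = as.numeric(m[, 3]), right = as.numeric(m[, 4]),
              value = as.numeric(m[, 5]))))
}

rf_from_list <- function(lst) {
  trees <- lapply(lst$trees, function(tr)
    cbind(unlist(tr$feature), unlist(tr$threshold), unlist(tr$left),
          unlist(tr$right), unlist(tr$value)))
  structure(list(trees = trees, n_features = as.integer(lst$n_features),
                 n_estimators = as.integer(lst$n_estimators),
                 max_depth = as.integer(lst$max_depth),
                 seed = as.integer(lst$seed)),
            class = "ms2_rf")
}
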