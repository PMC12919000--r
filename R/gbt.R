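# R interface to the boosted-tree engine in src/gbt.cpp.

#' Fit a gradient-boosted tree classifier
#'
#' Second-order gradient boosting with logistic loss, exact greedy splits and
#' L2-regularised leaf weights. Deterministic for fixed inputs (no row or
#' column subsampling).
#'
#' @param x numeric matrix (rows = samples); column names become feature names
#' @param y 0/1 numeric vector
#' @param nrounds number of trees
#' @param eta learning rate
#' @param max_depth maximum tree depth
#' @param lambda L2 regularisation on leaf weights
#' @param gamma minimum gain to split
#' @param min_child_weight minimum hessian sum per child
#' @param colsample_bytree fraction of features offered to each tree
#'   (deterministic internal sampler; decorrelates trees)
#' @param sample_seed seed for the column sampler (independent of R's RNG)
#' @return a `gbt_model`: trees, base_margin, eta, importance (named total
#'   gain), feature_names, params
#' @export
gbt_fit <- function(x, y, nrounds = 100L, eta = 0.1, max_depth = 3L,
                    lambda = 1.0, gamma = 0.0, min_child_weight = 1.0,
                    colsample_bytree = 0.7, sample_seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (anyNA(x)) stop("gbt_fit does not accept missing feature values")
  base <- min(max(mean(y), 1e-6), 1 - 1e-6)
  fit <- .gbt_train_cpp(x, y, as.integer(nrounds), eta, as.integer(max_depth),
                        lambda, gamma, min_child_weight, base,
                        colsample_bytree, as.integer(sample_seed))
  imp <- stats::setNames(fit$importance,
                         colnames(x) %||% paste0("f", seq_len(ncol(x))))
  structure(list(trees = fit$trees, base_margin = fit$base_margin, eta = eta,
                 importance = imp,
                 feature_names = names(imp),
                 params = list(nrounds = nrounds, eta = eta,
                               max_depth = max_depth, lambda = lambda,
                               gamma = gamma,
                               min_child_weight = min_child_weight,
                               colsample_bytree = colsample_bytree,
                               sample_seed = sample_seed)),
            class = "gbt_model")
}

#' Predict from a gbt_model
#' @param object a `gbt_model`
#' @param newdata numeric matrix or data.frame with the model's feature columns
#' @param type `"response"` (probability) or `"margin"`
#' @param ... unused
#' @return numeric vector
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "margin"),
                              ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else if (!is.null(colnames(newdata)) &&
             all(object$feature_names %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  storage.mode(newdata) <- "double"
  m <- .gbt_margin_cpp(object$trees, object$base_margin, object$eta, newdata)
  if (type == "margin") m else 1 / (1 + exp(-m))
}

# JSON-safe representation (trees as row-major numeric lists).
gbt_to_list <- function(model) {
  list(trees = lapply(model$trees, function(tm) {
         list(nrow = nrow(tm), data = as.numeric(t(tm)))
       }),
       base_margin = model$base_margin, eta = model$eta,
       importance = as.list(model$importance),
       feature_names = model$feature_names, params = model$params)
}

gbt_from_list <- function(lst) {
  trees <- lapply(lst$trees, function(t) {
    matrix(as.numeric(t$data), nrow = t$nrow, byrow = TRUE)
  })
  structure(list(trees = trees, base_margin = lst$base_margin, eta = lst$eta,
                 importance = stats::setNames(unlist(lst$importance),
                                              names(lst$importance)),
                 feature_names = unlist(lst$feature_names),
                 params = lst$params),
            class = "gbt_model")
}
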