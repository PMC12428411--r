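#' Fit one classifier
#'
#' The three learner kinds of the benchmark, wrapped behind a uniform
#' deterministic surface:
#'
#' * `"bagged_trees"` — a random forest ([ranger::ranger()]): bootstrap
#'   ensemble of decision trees predicting by vote.
#' * `"boosted_trees"` — extreme gradient boosting
#'   ([xgboost::xgb.train()]): trees built sequentially, each improving
#'   the previous ensemble's prediction.
#' * `"linear"` — ridge-regularized (multinomial) logistic regression
#'   ([glmnet::glmnet()]): the linear baseline.
#'
#' Hyperparameters are fixed, sensible defaults (no tuning is performed):
#' 500 trees for the forest; depth 3, learning rate 0.1, 100 rounds for
#' boosting; ridge penalty 0.01 for the linear model.
#'
#' @param learner One of `"linear"`, `"bagged_trees"`, `"boosted_trees"`.
#' @param x Numeric feature matrix.
#' @param y Class vector (>= 2 classes present).
#' @param seed Integer seed; refitting with the same data and seed gives
#'   identical predictions.
#' @param num_trees,max_depth,eta,nrounds,lambda Hyperparameters (see
#'   above).
#' @return A `prrt_model`; `predict(model, x)` returns a factor with the
#'   training levels.
#' @export
train_model <- function(learner = c("bagged_trees", "boosted_trees", "linear"),
                        x, y, seed = 1L, num_trees = 500L, max_depth = 3L,
                        eta = 0.1, nrounds = 100L, lambda = 0.01) {
  learner <- match.arg(learner)
  stop_if_not(is.matrix(x) && is.numeric(x), "`x` must be a numeric matrix.")
  y <- factor(y)
  stop_if_not(nlevels(droplevels(y)) >= 2,
              "Training labels contain a single class.")
  y <- droplevels(y)
  lv <- levels(y)

  fit <- switch(
    learner,
    bagged_trees = {
      df <- as.data.frame(x)
      ranger::ranger(
        y = y, x = df, num.trees = num_trees, seed = as.integer(seed),
        num.threads = 1L, respect.unordered.factors = "order"
      )
    },
    boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      params <- if (length(lv) == 2) {
        list(objective = "binary:logistic", max_depth = max_depth, eta = eta,
             nthread = 1L, seed = as.integer(seed))
      } else {
        list(objective = "multi:softmax", num_class = length(lv),
             max_depth = max_depth, eta = eta, nthread = 1L,
             seed = as.integer(seed))
      }
      xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                         verbose = 0)
    },
    linear = {
      fam <- if (length(lv) == 2) "binomial" else "multinomial"
      glmnet::glmnet(x, y, family = fam, alpha = 0,
                     lambda = c(10, 1, 0.1, lambda), standardize = TRUE)
    }
  )
  structure(
    list(learner = learner, fit = fit, levels = lv, lambda = lambda,
         n_features = ncol(x), feature_names = colnames(x)),
    class = "prrt_model"
  )
}

#' @export
predict.prrt_model <- function(object, newdata, ...) {
  stop_if_not(is.matrix(newdata) && ncol(newdata) == object$n_features,
              "`newdata` must be a matrix with the training columns.")
  lv <- object$levels
  out <- switch(
    object$learner,
    bagged_trees = {
      p <- predict(object$fit, data = as.data.frame(newdata),
                   num.threads = 1L)$predictions
      as.character(p)
    },
    boosted_trees = {
      p <- predict(object$fit, newdata)
      if (length(lv) == 2) lv[1L + as.integer(p > 0.5)] else lv[1L + as.integer(p)]
    },
    linear = {
      p <- predict(object$fit, newx = newdata, s = object$lambda,
                   type = "class")
      as.character(p)
    }
  )
  factor(out, levels = lv)
}

#' @export
print.prrt_model <- function(x, ...) {
  cat("<prrt_model> ", x$learner, ", ", length(x$levels), " classes, ",
      x$n_features, " features\n", sep = "")
  invisible(x)
}
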