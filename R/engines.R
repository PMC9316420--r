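#' Binary classifier contract for discrete hazard estimation
#'
#' Any binary classifier can estimate the per-interval hazard from the
#' person-period table. An engine bundles a `fit` function, a probability
#' `predict` function, default parameters and an optional hyperparameter
#' search grid. [dtsurv()] handles feature construction (standardized
#' covariates plus an encoded interval identifier); the engine only sees a
#' numeric feature matrix and a 0/1 outcome.
#'
#' @param name short engine label.
#' @param fit `function(x, y, seed, params)` returning an opaque fitted
#'   state; must be reproducible given `seed`.
#' @param predict `function(state, x)` returning one probability in
#'   \eqn{[0,1]} per row of `x`.
#' @param params named list of default hyperparameter values.
#' @param grid named list of candidate value vectors for tuning; names must
#'   be a subset of `names(params)`.
#' @return an object of class `"dtsurv_engine"`.
#' @seealso [engine_glm()], [engine_ranger()], [engine_rpart()]
#' @export
dtsurv_engine <- function(name, fit, predict, params = list(),
                          grid = list()) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  if (!all(names(grid) %in% names(params))) {
    stop("grid entries must name parameters declared in params", call. = FALSE)
  }
  structure(list(name = name, fit = fit, predict = predict,
                 params = params, grid = grid),
            class = "dtsurv_engine")
}

#' @export
print.dtsurv_engine <- function(x, ...) {
  cat("Classifier engine:", x$name, "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(lapply(x$params, deparse)),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Logistic-regression classifier engine
#'
#' Plain maximum-likelihood logistic regression through the classifier
#' contract. On identical features this reproduces the logit link model and
#' serves as a cross-check between the parametric and classifier paths.
#'
#' @return a [dtsurv_engine()].
#' @export
engine_glm <- function() {
  dtsurv_engine(
    name = "glm",
    fit = function(x, y, seed, params) {
      fit <- suppressWarnings(
        stats::glm.fit(x, y, family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    predict = function(state, x) {
      as.numeric(stats::plogis(drop(x %*% state$coef)))
    })
}

#' Random-forest classifier engine
#'
#' Probability forest via \pkg{ranger}, single-threaded and seeded for
#' reproducibility. Suits the ordinal interval encoding, which lets trees
#' split follow-up time at data-driven points.
#'
#' @param num.trees,mtry,min.node.size usual forest hyperparameters; `mtry`
#'   `NULL` uses the ranger default (floor of sqrt(p)).
#' @return a [dtsurv_engine()].
#' @export
engine_ranger <- function(num.trees = 300, mtry = NULL, min.node.size = 10) {
  dtsurv_engine(
    name = "ranger",
    fit = function(x, y, seed, params) {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(
        dependent.variable.name = ".y", data = df, probability = TRUE,
        num.trees = params$num.trees, mtry = params$mtry,
        min.node.size = params$min.node.size,
        seed = if (is.null(seed)) 1L else seed, num.threads = 1)
    },
    predict = function(state, x) {
      p <- stats::predict(state, data = as.data.frame(x),
                          num.threads = 1)$predictions
      as.numeric(p[, "1"])
    },
    params = list(num.trees = num.trees, mtry = mtry,
                  min.node.size = min.node.size),
    grid = list(min.node.size = c(5, 10, 25, 50)))
}

#' Classification-tree engine
#'
#' Single CART tree via \pkg{rpart}; deterministic, mainly useful as a fast
#' nonlinear baseline in tests and examples.
#'
#' @param cp complexity parameter.
#' @param minbucket minimum terminal-node size.
#' @return a [dtsurv_engine()].
#' @export
engine_rpart <- function(cp = 0.005, minbucket = 20) {
  dtsurv_engine(
    name = "rpart",
    fit = function(x, y, seed, params) {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp, minbucket = params$minbucket))
    },
    predict = function(state, x) {
      as.numeric(stats::predict(state, newdata = as.data.frame(x),
                                type = "prob")[, "1"])
    },
    params = list(cp = cp, minbucket = minbucket),
    grid = list(cp = c(0.001, 0.005, 0.02)))
}
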