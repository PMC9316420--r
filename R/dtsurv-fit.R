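#' Fit a discrete-time survival prediction model
#'
#' Fits the discrete-time hazard \eqn{\lambda_j(x) = \Pr(T \in A_j \mid T >
#' t_{j-1}, X = x)} by binary classification on the person-period expansion
#' of right-censored follow-up data. With a link function, the model is
#' \deqn{g(\lambda_{ij}) = \alpha_j + \beta X_i,}
#' fitted by maximum likelihood with standard binomial GLM machinery applied
#' to the person-period rows; `link = "logit"` is the continuation-ratio
#' model and `link = "cloglog"` the grouped proportional-hazards model (the
#' discrete-time analogue of the Cox model). With a classifier `engine`, any
#' binary classification method predicts the hazard from the covariates and
#' an encoded interval identifier, \eqn{\lambda_{ij} = f(X_i, A_j)}.
#' Predicted hazards compose into the survival curve
#' \deqn{S(t \mid x) = \prod_{j : t_j \le t} (1 - \lambda_j(x)).}
#'
#' The interval grid defaults to event-time quantile cut points within the
#' horizon ([quantile_grid()]); follow-up is administratively censored at
#' the horizon first. For classifier engines, covariates are standardized by
#' the training subjects' means and standard deviations (computed over
#' subjects, not person-period rows, since covariates are time-fixed), and
#' the interval identifier is one-hot encoded by default (`encoding =
#' "ordinal"` passes the integer index instead, convenient for trees). Link
#' models are fit on the raw covariate scale so coefficients stay
#' interpretable.
#'
#' @param formula a formula with a `survival::Surv(time, event)` response
#'   and baseline covariate terms.
#' @param data a data frame (or [survival_data()]) with one row per subject.
#' @param horizon prediction horizon \eqn{w > 0}; required unless `grid` is
#'   supplied.
#' @param n_intervals requested number of intervals \eqn{J} for the quantile
#'   grid (ignored when `grid` is given).
#' @param grid an [interval_grid()] overriding the quantile construction.
#' @param link link function for the parametric model: one of `"logit"`,
#'   `"cloglog"`, `"probit"`, `"loglog"`, `"log"`. Ignored when `engine` is
#'   supplied.
#' @param engine a [dtsurv_engine()] classifier, or `NULL` for the link
#'   model.
#' @param censoring censoring specification for the person-period expansion;
#'   see [person_period()].
#' @param encoding interval encoding for classifier engines: `"onehot"` or
#'   `"ordinal"`.
#' @param params named list overriding the engine's default hyperparameters.
#' @param seed integer seed threaded to the engine for reproducible fits.
#'
#' @return an object of class `"dtsurv"` with `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `plot` and `simulate` methods.
#' @examples
#' set.seed(1)
#' sim <- simulate_survival(n = 300, family = "exponential", beta = 0.7,
#'                          base_rate = 0.2, censor_rate = 0.3, seed = 1)
#' fit <- dtsurv(survival::Surv(time, event) ~ x1, data = sim,
#'               horizon = 8, n_intervals = 6, link = "cloglog")
#' predict(fit, data.frame(x1 = c(-1, 1)), times = c(2, 4, 8))
#' @export
dtsurv <- function(formula, data, horizon = NULL, n_intervals = 10,
                   grid = NULL, link = "logit", engine = NULL,
                   censoring = c("observed", "half", "full"),
                   encoding = c("onehot", "ordinal"),
                   params = list(), seed = NULL) {
  cl <- match.call()
  censoring <- match.arg(censoring)
  encoding <- match.arg(encoding)
  if (is.null(grid) && is.null(horizon)) {
    stop("supply either 'horizon' or an explicit 'grid'", call. = FALSE)
  }

  mf <- stats::model.frame(formula, data = as.data.frame(data))
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right") {
    stop("response must be a right-censored survival::Surv(time, event) object",
         call. = FALSE)
  }
  tr <- stats::delete.response(stats::terms(formula, data = as.data.frame(data)))
  xlev <- stats::.getXlevels(stats::terms(mf), mf)
  X <- stats::model.matrix(tr, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  # ncol(X) == 0 is allowed: an intercept-only fit is the saturated-in-time
  # life-table model
  sdat <- survival_data(
    data.frame(.time = as.numeric(y[, "time"]),
               .event = as.numeric(y[, "status"]), X, check.names = FALSE),
    time = ".time", event = ".event", covariates = colnames(X))

  if (is.null(grid)) {
    sdat <- admin_censor(sdat, horizon)
    grid <- quantile_grid(sdat, horizon, n_intervals)
  } else {
    stopifnot(inherits(grid, "interval_grid"))
    sdat <- admin_censor(sdat, grid$horizon)
  }
  pp <- person_period(sdat, grid, censoring)
  if (sum(pp$d) == 0L) {
    stop("person-period table contains no failures; nothing to fit",
         call. = FALSE)
  }

  covs <- colnames(X)
  obj <- list(call = cl, formula = formula, terms = tr, xlevels = xlev,
              covariates = covs, grid = grid, censoring = censoring,
              encoding = encoding, seed = seed, pp = pp,
              n = nrow(sdat), n_events = sum(sd_event(sdat)),
              dropped = attr(pp, "dropped"),
              cov_means = colMeans(sd_covs(sdat)))

  if (is.null(engine)) {
    obj$type <- "link"
    obj$link <- match.arg(link, dt_links)
    obj$fit <- fit_link_glm(pp, covs, obj$link)
    obj$coefficients <- stats::coef(obj$fit)
  } else {
    stopifnot(inherits(engine, "dtsurv_engine"))
    obj$type <- "engine"
    obj$engine <- engine
    obj$params <- utils::modifyList(engine$params, params)
    obj$center <- colMeans(sd_covs(sdat))
    scl <- apply(sd_covs(sdat), 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    obj$scale <- scl
    feats <- engine_features(pp, obj)
    state <- tryCatch(
      engine$fit(feats, pp$d, seed = seed, params = obj$params),
      error = function(e) stop("classifier engine '", engine$name,
                               "' failed during fit: ", conditionMessage(e),
                               call. = FALSE))
    obj$state <- state
  }
  class(obj) <- "dtsurv"
  obj
}

# maximum-likelihood fit of g(lambda) = alpha_j + beta X on person-period rows
fit_link_glm <- function(pp, covs, link) {
  J <- attr(pp, "grid")$n_intervals
  dat <- data.frame(d = pp$d,
                    stats::model.matrix(~ 0 + interval_label, pp),
                    check.names = FALSE)
  names(dat)[-1] <- paste0("A", seq_len(J))
  dat <- cbind(dat, as.data.frame(pp)[, covs, drop = FALSE])
  fml <- stats::reformulate(sprintf("`%s`", c(paste0("A", seq_len(J)), covs)),
                            response = "d", intercept = FALSE)
  # the log link needs a valid starting point (eta < 0 so that lambda < 1)
  start <- if (link == "log") {
    c(rep(log(max(mean(pp$d), 1e-3)), J), rep(0, length(covs)))
  } else NULL
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = dt_family(link), model = FALSE,
               start = start),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  alpha <- cf[seq_len(J)]
  if (anyNA(alpha)) {
    stop("interval(s) ", paste(which(is.na(alpha)), collapse = ", "),
         " have no at-risk rows; refit with fewer intervals", call. = FALSE)
  }
  if (anyNA(cf)) {
    stop("covariates are collinear on the person-period table: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (!fit$converged) {
    stop("hazard model did not converge (possible complete separation); ",
         "deviance = ", signif(fit$deviance, 6), call. = FALSE)
  }
  fit
}

# feature matrix seen by classifier engines: encoded interval + scaled covariates
engine_features <- function(pp, obj) {
  J <- obj$grid$n_intervals
  Xc <- sweep(sweep(as.matrix(as.data.frame(pp)[, obj$covariates,
                                                drop = FALSE]),
                    2, obj$center, "-"), 2, obj$scale, "/")
  if (obj$encoding == "onehot") {
    enc <- stats::model.matrix(~ 0 + interval_label, pp)
    colnames(enc) <- paste0("A", seq_len(J))
  } else {
    enc <- matrix(pp$interval, ncol = 1, dimnames = list(NULL, "interval"))
  }
  cbind(enc, Xc)
}

# covariate model matrix for new subjects, on the training schema
newdata_matrix <- function(object, newdata) {
  mfn <- stats::model.frame(object$terms, as.data.frame(newdata),
                            xlev = object$xlevels, na.action = stats::na.fail)
  X <- stats::model.matrix(object$terms, mfn)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!identical(colnames(X), object$covariates)) {
    stop("newdata covariates do not match the training schema",
         call. = FALSE)
  }
  X
}

# per-row hazards for an existing person-period table (likelihood evaluation)
row_hazards <- function(object, pp) {
  if (object$type == "link") {
    cf <- object$coefficients
    J <- object$grid$n_intervals
    alpha <- cf[seq_len(J)]
    beta <- cf[-seq_len(J)]
    Xr <- as.matrix(as.data.frame(pp)[, object$covariates, drop = FALSE])
    eta <- alpha[pp$interval] + drop(Xr %*% beta)
    as.numeric(dt_linkinv(object$link)(eta))
  } else {
    p <- object$engine$predict(object$state, engine_features(pp, object))
    check_probabilities(p, object$engine$name)
    p
  }
}

check_probabilities <- function(p, name) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("classifier engine '", name,
         "' violated the contract: probabilities outside [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

#' Predict hazards, survival or event probabilities
#'
#' Applies the stored preprocessing, expands each new subject to one row per
#' interval, predicts the conditional failure probability
#' \eqn{\lambda_j(x)} for every interval and, for `type = "survival"` or
#' `"risk"`, composes the step survival curve
#' \eqn{S(t|x) = \prod_{j: t_j \le t}(1-\lambda_j(x))} evaluated at `times`.
#' Hazards are clipped to \eqn{[10^{-6}, 1-10^{-6}]} before composition so a
#' single confident classification cannot collapse the whole curve to 0.
#'
#' @param object a fitted [dtsurv()] model.
#' @param newdata data frame of baseline covariates (training schema).
#' @param type `"survival"` for \eqn{S(t)}, `"risk"` for the event
#'   probability \eqn{p(t) = 1 - S(t)}, `"hazard"` for the per-interval
#'   \eqn{\lambda_j}.
#' @param times evaluation times in \eqn{[0, w]}; defaults to the grid cut
#'   points \eqn{t_1, \dots, t_J}. Times beyond the horizon are refused
#'   (no extrapolation).
#' @param ... unused.
#' @return a numeric matrix, subjects in rows; columns are `times`
#'   (survival/risk) or intervals (hazard).
#' @export
predict.dtsurv <- function(object, newdata,
                           type = c("survival", "risk", "hazard"),
                           times = NULL, ...) {
  type <- match.arg(type)
  X <- newdata_matrix(object, newdata)
  n <- nrow(X)
  J <- object$grid$n_intervals

  if (object$type == "link") {
    cf <- object$coefficients
    alpha <- cf[seq_len(J)]
    beta <- cf[-seq_len(J)]
    eta <- outer(drop(X %*% beta), alpha, "+")
    lam <- matrix(dt_linkinv(object$link)(eta), nrow = n)
  } else {
    pp <- expand_prediction(as.data.frame(X), object$grid,
                            covariates = object$covariates)
    p <- object$engine$predict(object$state, engine_features(pp, object))
    check_probabilities(p, object$engine$name)
    lam <- matrix(p, nrow = n, byrow = TRUE)
  }
  lam <- pmin(pmax(lam, 1e-6), 1 - 1e-6)
  colnames(lam) <- paste0("A", seq_len(J))
  if (type == "hazard") return(lam)

  if (is.null(times)) times <- object$grid$cut_points[-1L]
  if (any(times < 0) || any(times > object$grid$horizon)) {
    stop("evaluation times must lie in [0, horizon]; refusing to extrapolate",
         call. = FALSE)
  }
  logS <- t(apply(log1p(-lam), 1L, cumsum))
  if (n == 1L) logS <- matrix(logS, nrow = 1L)
  k <- findInterval(times, object$grid$cut_points[-1L])
  S <- cbind(1, exp(logS))[, k + 1L, drop = FALSE]
  dimnames(S) <- list(NULL, paste0("t=", signif(times, 6)))
  if (type == "risk") 1 - S else S
}

#' Discrete-time survival log-likelihood
#'
#' Evaluates \eqn{\sum_{rows} d \log\lambda + (1-d)\log(1-\lambda)} on a
#' person-period table, which equals the subject-level discrete survival
#' likelihood (each subject contributing
#' \eqn{\lambda_{j_i}^{\delta_i}\prod_{j<j_i}(1-\lambda_{ij})}-type terms).
#' Hazards are clipped to \eqn{[10^{-12}, 1-10^{-12}]}; if clipping occurs a
#' warning reports how many rows were affected.
#'
#' @param object a fitted [dtsurv()] model.
#' @param table a [person_period()] table; defaults to the training table.
#' @return the log-likelihood (numeric scalar).
#' @export
hazard_loglik <- function(object, table = NULL) {
  stopifnot(inherits(object, "dtsurv"))
  if (is.null(table)) table <- object$pp
  lam <- row_hazards(object, table)
  n_clip <- sum(lam < 1e-12 | lam > 1 - 1e-12)
  if (n_clip > 0) {
    warning(n_clip, " hazard(s) clipped to [1e-12, 1-1e-12] in likelihood",
            call. = FALSE)
  }
  lam <- pmin(pmax(lam, 1e-12), 1 - 1e-12)
  sum(table$d * log(lam) + (1 - table$d) * log1p(-lam))
}

#' @export
logLik.dtsurv <- function(object, ...) {
  val <- hazard_loglik(object)
  structure(val,
            df = if (object$type == "link")
              length(object$coefficients) else NA_integer_,
            nobs = nrow(object$pp), class = "logLik")
}

#' @export
coef.dtsurv <- function(object, ...) {
  if (object$type != "link") {
    warning("coefficients are only defined for link-based models",
            call. = FALSE)
    return(NULL)
  }
  object$coefficients
}

#' @export
print.dtsurv <- function(x, ...) {
  cat("Discrete-time survival model\n")
  cat(sprintf("  %s, J = %d intervals on (0, %g], censoring = '%s'\n",
              if (x$type == "link") paste0("link = ", x$link)
              else paste0("engine = ", x$engine$name),
              x$grid$n_intervals, x$grid$horizon, x$censoring))
  cat(sprintf("  %d subjects (%d events), %d person-period rows\n",
              x$n, x$n_events, nrow(x$pp)))
  if (x$type == "link") {
    cat("Coefficients:\n")
    print(signif(x$coefficients, 4))
  }
  invisible(x)
}

#' @param object a fitted [dtsurv()] model.
#' @param ... unused.
#' @rdname dtsurv
#' @export
summary.dtsurv <- function(object, ...) {
  out <- list(call = object$call, type = object$type, grid = object$grid,
              censoring = object$censoring, n = object$n,
              n_events = object$n_events, n_rows = nrow(object$pp),
              dropped = length(object$dropped))
  if (object$type == "link") {
    out$link <- object$link
    out$coefficients <- stats::coef(summary(object$fit))
    out$loglik <- as.numeric(logLik(object))
  } else {
    out$engine <- object$engine$name
    out$params <- object$params
  }
  class(out) <- "summary.dtsurv"
  out
}

#' @export
print.summary.dtsurv <- function(x, ...) {
  cat("Discrete-time survival model\n\nCall:\n")
  print(x$call)
  cat(sprintf("\nJ = %d intervals on (0, %g], censoring = '%s'\n",
              x$grid$n_intervals, x$grid$horizon, x$censoring))
  cat(sprintf("%d subjects (%d events), %d person-period rows",
              x$n, x$n_events, x$n_rows))
  if (x$dropped > 0) cat(sprintf(", %d subjects dropped", x$dropped))
  cat("\n")
  if (!is.null(x$coefficients)) {
    cat(sprintf("\nLink: %s   log-likelihood: %.3f\nCoefficients:\n",
                x$link, x$loglik))
    stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  } else {
    cat("\nClassifier engine:", x$engine, "\n")
  }
  invisible(x)
}

#' @param x a fitted model (for `plot`).
#' @param newdata subjects whose predicted survival curves to draw; defaults
#'   to a single subject at the training covariate means.
#' @rdname dtsurv
#' @export
plot.dtsurv <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- as.data.frame(as.list(x$cov_means), check.names = FALSE)
    # cov_means are on the model-matrix scale already; bypass the formula
    X <- matrix(x$cov_means, nrow = 1,
                dimnames = list(NULL, x$covariates))
    newdata <- as.data.frame(X, check.names = FALSE)
    S <- predict_from_matrix(x, X)
  } else {
    S <- predict(x, newdata, type = "survival")
  }
  tj <- x$grid$cut_points
  graphics::plot(NULL, xlim = c(0, x$grid$horizon), ylim = c(0, 1),
                 xlab = "time", ylab = "S(t)",
                 main = "Predicted survival", ...)
  for (i in seq_len(nrow(S))) {
    graphics::lines(stats::stepfun(tj[-1L], c(1, S[i, ])), do.points = FALSE,
                    col = i)
  }
  invisible(x)
}

# survival at grid cut points from a raw model-matrix row (plot helper)
predict_from_matrix <- function(object, X) {
  J <- object$grid$n_intervals
  if (object$type == "link") {
    cf <- object$coefficients
    eta <- outer(drop(X %*% cf[-seq_len(J)]), cf[seq_len(J)], "+")
    lam <- matrix(dt_linkinv(object$link)(eta), nrow = nrow(X))
  } else {
    pp <- expand_prediction(as.data.frame(X), object$grid,
                            covariates = object$covariates)
    lam <- matrix(object$engine$predict(object$state,
                                        engine_features(pp, object)),
                  nrow = nrow(X), byrow = TRUE)
  }
  lam <- pmin(pmax(lam, 1e-6), 1 - 1e-6)
  t(apply(1 - lam, 1L, cumprod))
}

#' Simulate event intervals from a fitted discrete hazard model
#'
#' Draws discrete event times from the model's own predicted hazards by
#' sequential Bernoulli trials over the intervals; subjects surviving all
#' \eqn{J} intervals are censored at the horizon. Useful for parametric-
#' bootstrap style checks.
#'
#' @param object a fitted [dtsurv()] model.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param newdata covariates of the subjects to simulate; defaults to
#'   resimulating the training subjects.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `time` (right endpoint
#'   of the event interval, or the horizon) and `event`.
#' @export
simulate.dtsurv <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) {
    first <- !duplicated(object$pp$id)
    X <- as.matrix(as.data.frame(object$pp)[first, object$covariates,
                                            drop = FALSE])
    lamfun <- function() predict_hazard_matrix(object, X)
  } else {
    lamfun <- function() predict(object, newdata, type = "hazard")
  }
  lam <- lamfun()
  J <- ncol(lam)
  hi <- object$grid$cut_points[-1L]
  lapply(seq_len(nsim), function(s) {
    u <- matrix(stats::runif(length(lam)), nrow = nrow(lam))
    fail <- u < lam
    j <- apply(fail, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
    data.frame(time = ifelse(is.na(j), object$grid$horizon, hi[j]),
               event = as.integer(!is.na(j)))
  })
}

predict_hazard_matrix <- function(object, X) {
  J <- object$grid$n_intervals
  if (object$type == "link") {
    cf <- object$coefficients
    lam <- matrix(dt_linkinv(object$link)(
      outer(drop(X %*% cf[-seq_len(J)]), cf[seq_len(J)], "+")),
      nrow = nrow(X))
  } else {
    pp <- expand_prediction(as.data.frame(X), object$grid,
                            covariates = object$covariates)
    lam <- matrix(object$engine$predict(object$state,
                                        engine_features(pp, object)),
                  nrow = nrow(X), byrow = TRUE)
  }
  pmin(pmax(lam, 1e-6), 1 - 1e-6)
}
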