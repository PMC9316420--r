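#' Subject-level data-splitting plans
#'
#' Declares how subjects are partitioned for model building and testing:
#' either a holdout train/validation/test split (default 60/20/20) or
#' (repeated) K-fold cross-validation. Splits are made at the subject level
#' and, by default, stratified by the event indicator so small data sets do
#' not produce event-free folds.
#'
#' @param scheme `"holdout"` or `"kfold"`.
#' @param frac holdout fractions `c(train, validation, test)`, positive and
#'   summing to 1.
#' @param k number of folds (\eqn{\ge 2}).
#' @param repeats number of independent repetitions of the K-fold split.
#' @param stratify stratify by event indicator.
#' @return an object of class `"split_plan"`.
#' @export
split_plan <- function(scheme = c("holdout", "kfold"),
                       frac = c(train = 0.6, validation = 0.2, test = 0.2),
                       k = 5, repeats = 1, stratify = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "holdout") {
    stopifnot(length(frac) == 3, all(frac > 0),
              isTRUE(all.equal(sum(frac), 1)))
  } else {
    stopifnot(k >= 2, repeats >= 1)
  }
  structure(list(scheme = scheme, frac = frac, k = k, repeats = repeats,
                 stratify = stratify), class = "split_plan")
}

# largest-remainder apportionment of n units to groups with given weights
alloc_counts <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# randomly assign subjects to groups with exact global counts, balanced
# across strata (largest-remainder apportionment plus a repair pass)
stratified_assign <- function(strata, global_counts, labels, seed) {
  set.seed(seed)
  present <- which(tabulate(strata) > 0)
  ns <- tabulate(strata)[present]
  M <- alloc_stratified(ns, global_counts)
  out <- vector(mode = typeof(labels), length(strata))
  for (si in seq_along(present)) {
    idx <- sample(which(strata == present[si]))
    out[idx] <- rep(labels, times = M[si, ])
  }
  out
}

# per-stratum group counts whose column sums match the global targets exactly
alloc_stratified <- function(ns, global) {
  M <- t(vapply(ns, function(n_s) alloc_counts(n_s, global),
                integer(length(global))))
  repeat {
    diff <- colSums(M) - global
    if (all(diff == 0)) break
    a <- which.max(diff)
    b <- which.min(diff)
    s <- which.max(ifelse(M[, a] > 0, M[, a], -1L))
    M[s, a] <- M[s, a] - 1L
    M[s, b] <- M[s, b] + 1L
  }
  M
}

#' Assign subjects to splits
#'
#' Deterministic given `seed`. Holdout returns a factor with levels
#' `train`/`validation`/`test` whose sizes match the plan fractions exactly
#' (largest-remainder apportionment, balanced across event strata); K-fold
#' returns an integer matrix (subjects x repeats) of fold memberships with
#' fold sizes differing by at most one.
#'
#' @param x a data frame or [survival_data()]; stratification uses its
#'   event column (`event` by default for plain data frames).
#' @param plan a [split_plan()].
#' @param seed integer seed.
#' @param event event column name when `x` is a plain data frame.
#' @return see Description.
#' @export
make_splits <- function(x, plan, seed = 1, event = "event") {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(x)
  ev <- if (inherits(x, "survival_data")) sd_event(x) else x[[event]]
  strata <- if (plan$stratify && !is.null(ev) && length(unique(ev)) > 1L) {
    as.integer(factor(ev))
  } else rep(1L, n)

  if (plan$scheme == "holdout") {
    counts <- alloc_counts(n, plan$frac)
    if (any(counts == 0)) {
      stop("a holdout split would be empty; use larger fractions or more data",
           call. = FALSE)
    }
    factor(stratified_assign(strata, counts,
                             c("train", "validation", "test"), seed),
           levels = c("train", "validation", "test"))
  } else {
    counts <- alloc_counts(n, rep(1, plan$k))
    if (any(counts == 0)) {
      stop("a fold would be empty; use fewer folds", call. = FALSE)
    }
    vapply(seq_len(plan$repeats),
           function(r) stratified_assign(strata, counts, seq_len(plan$k),
                                         seed + r),
           integer(n))
  }
}

#' Method specifications for tuning and benchmarking
#'
#' Small descriptors naming what to fit: a link-based discrete hazard model,
#' a classifier engine (with its hyperparameter search grid), the
#' Kaplan-Meier null predictor, or an externally supplied survival
#' predictor (e.g. a continuous-time model) evaluated on the same footing.
#'
#' @param link link function for [dtsurv()].
#' @param engine a [dtsurv_engine()].
#' @param encoding interval encoding for the engine.
#' @param grid hyperparameter search grid (named list of value vectors);
#'   defaults to the engine's own grid.
#' @param fit_fun for `method_external`: a
#'   `function(formula, train, newdata, times, seed)` returning a
#'   subjects x times matrix of predicted event probabilities for
#'   `newdata`.
#' @param label report label.
#' @return an object of class `"dtsurv_method"`.
#' @name dtsurv_method
NULL

#' @rdname dtsurv_method
#' @export
method_link <- function(link = "logit", label = paste0("link_", link)) {
  structure(list(type = "link", link = match.arg(link, dt_links),
                 grid = list(), label = label), class = "dtsurv_method")
}

#' @rdname dtsurv_method
#' @export
method_engine <- function(engine, encoding = c("onehot", "ordinal"),
                          grid = engine$grid, label = engine$name) {
  stopifnot(inherits(engine, "dtsurv_engine"))
  structure(list(type = "engine", engine = engine,
                 encoding = match.arg(encoding), grid = grid,
                 label = label), class = "dtsurv_method")
}

#' @rdname dtsurv_method
#' @export
method_null <- function(label = "null_km") {
  structure(list(type = "null", grid = list(), label = label),
            class = "dtsurv_method")
}

#' @rdname dtsurv_method
#' @export
method_external <- function(fit_fun, label = "external") {
  stopifnot(is.function(fit_fun))
  structure(list(type = "external", fit_fun = fit_fun, grid = list(),
                 label = label), class = "dtsurv_method")
}

# fit a method on `train` and return predicted event probabilities for
# `newdata` at `times`
fit_and_predict <- function(method, formula, train, newdata, times,
                            horizon, n_intervals, censoring, params,
                            seed) {
  if (method$type == "null") {
    y <- stats::model.response(stats::model.frame(formula, train))
    km <- km_curve(as.numeric(y[, "time"]), as.numeric(y[, "status"]))
    return(matrix(rep(1 - km$fun(times), each = nrow(newdata)),
                  nrow = nrow(newdata)))
  }
  if (method$type == "external") {
    return(method$fit_fun(formula, train, newdata, times, seed))
  }
  fit <- if (method$type == "link") {
    dtsurv(formula, train, horizon = horizon, n_intervals = n_intervals,
           link = method$link, censoring = censoring)
  } else {
    dtsurv(formula, train, horizon = horizon, n_intervals = n_intervals,
           engine = method$engine, encoding = method$encoding,
           params = params, censoring = censoring, seed = seed)
  }
  predict(fit, newdata, type = "risk", times = times)
}

# validation objective: Brier at a single time, or IBS over several
tuning_objective <- function(risk, times, time, event,
                             metric = c("brier", "ibs")) {
  metric <- match.arg(metric)
  risk <- as.matrix(risk)
  bs <- vapply(seq_along(times), function(k)
    td_brier(times[k], risk[, k], time, event), numeric(1))
  if (metric == "brier") {
    if (length(times) != 1L) {
      stop("metric 'brier' needs a single evaluation time; use 'ibs'",
           call. = FALSE)
    }
    bs
  } else {
    integrated_brier(times, bs)
  }
}

#' Tune a discrete-time method on a validation split
#'
#' Evaluates candidate configurations — the cross product of the number of
#' intervals and the method's hyperparameter grid — by fitting on the
#' training split and scoring the censoring-adjusted Brier objective on the
#' validation split, and returns the minimizer with the full trial log.
#' The number of intervals is itself a hyperparameter: the interval grid is
#' rebuilt from the training events for every candidate \eqn{J}.
#'
#' @param formula model formula with a `Surv` response.
#' @param train,val training and validation data frames.
#' @param horizon prediction horizon.
#' @param method a [method_link()] or [method_engine()] spec.
#' @param n_intervals candidate interval counts (default `2:25`; the
#'   ceiling of 25 keeps the person-period table and per-interval event
#'   counts manageable).
#' @param times evaluation time(s) for the objective.
#' @param metric `"brier"` (at a single time) or `"ibs"` (integrated over
#'   `times`).
#' @param censoring person-period censoring specification.
#' @param search `"grid"` evaluates every configuration; `"random"` samples
#'   `budget` of them.
#' @param budget number of configurations for random search.
#' @param seed root seed; per-trial engine seeds are derived from it.
#' @return an object of class `"dtsurv_tune"`: list with `best`
#'   (`n_intervals`, `params`, `objective`), `trials` (log data frame) and
#'   the method spec.
#' @export
tune_dtsurv <- function(formula, train, val, horizon, method,
                        n_intervals = 2:25, times,
                        metric = c("brier", "ibs"),
                        censoring = c("observed", "half", "full"),
                        search = c("grid", "random"), budget = NULL,
                        seed = 1) {
  metric <- match.arg(metric)
  censoring <- match.arg(censoring)
  search <- match.arg(search)
  stopifnot(inherits(method, "dtsurv_method"),
            method$type %in% c("link", "engine"))

  grid_list <- c(list(n_intervals = n_intervals), method$grid)
  grid_list <- grid_list[!vapply(grid_list, is.null, logical(1))]
  configs <- expand.grid(grid_list, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  if (search == "random") {
    if (is.null(budget)) budget <- min(20L, nrow(configs))
    set.seed(seed)
    configs <- configs[sample(nrow(configs),
                              min(budget, nrow(configs))), , drop = FALSE]
    rownames(configs) <- NULL
  }
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(configs))

  yv <- stats::model.response(stats::model.frame(formula, val))
  vt <- as.numeric(yv[, "time"])
  ve <- as.numeric(yv[, "status"])

  objective <- rep(NA_real_, nrow(configs))
  msg <- character(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    params <- as.list(configs[i, setdiff(names(configs), "n_intervals"),
                              drop = FALSE])
    res <- tryCatch({
      risk <- fit_and_predict(method, formula, train, val, times,
                              horizon, configs$n_intervals[i], censoring,
                              params, trial_seeds[i])
      tuning_objective(risk, times, vt, ve, metric)
    }, error = function(e) e)
    if (inherits(res, "error")) msg[i] <- conditionMessage(res)
    else objective[i] <- res
  }
  if (all(is.na(objective))) {
    stop("all tuning trials failed:\n  ",
         paste(unique(msg[msg != ""]), collapse = "\n  "), call. = FALSE)
  }
  trials <- cbind(configs, objective = objective, error = msg,
                  seed = trial_seeds)
  best_i <- which.min(objective)
  best <- list(
    n_intervals = configs$n_intervals[best_i],
    params = as.list(configs[best_i, setdiff(names(configs),
                                             "n_intervals"), drop = FALSE]),
    objective = objective[best_i], seed = trial_seeds[best_i])
  structure(list(best = best, trials = trials, method = method,
                 metric = metric, times = times), class = "dtsurv_tune")
}

#' @export
print.dtsurv_tune <- function(x, ...) {
  cat(sprintf("Tuning result for '%s' (%d trials, objective: %s)\n",
              x$method$label, nrow(x$trials), x$metric))
  cat("  best: n_intervals =", x$best$n_intervals)
  if (length(x$best$params)) {
    cat(",", paste(names(x$best$params),
                   vapply(x$best$params, format, ""), sep = "=",
                   collapse = ", "))
  }
  cat(sprintf("  (objective %.5f)\n", x$best$objective))
  invisible(x)
}
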