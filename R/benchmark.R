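#' Benchmark survival prediction methods
#'
#' Runs the full model building and testing pipeline for each declared
#' method: split the data by subject, tune hyperparameters (including the
#' number of intervals) on the validation data, refit with the tuned
#' configuration, predict event probabilities on held-out subjects and
#' score them with the censoring-adjusted metrics. Under a holdout plan the
#' tuned model is refit on the training split only (so the validation
#' objective stays honest; `refit = "train_val"` refits on train +
#' validation). Under K-fold cross-validation each fold is held out in
#' turn, tuning uses an inner 75/25 train/validation split of the remaining
#' folds, the tuned model is refit on all remaining folds, and metrics are
#' averaged across folds and repeats.
#'
#' All randomness flows from the single `seed`, expanded deterministically
#' per component; two runs with the same inputs produce identical reports.
#'
#' @param formula model formula with a `survival::Surv` response.
#' @param data subject-level data frame.
#' @param horizon prediction horizon.
#' @param methods named list of [dtsurv_method] specs.
#' @param times evaluation times for the metrics (and the tuning
#'   objective).
#' @param metric tuning objective: `"brier"` (single time) or `"ibs"`.
#' @param plan a [split_plan()].
#' @param n_intervals candidate interval counts for tuning.
#' @param censoring person-period censoring specification.
#' @param search,budget hyperparameter search strategy, see
#'   [tune_dtsurv()].
#' @param refit holdout refit policy.
#' @param seed root seed.
#' @return an object of class `"dtsurv_benchmark"`: per-method results
#'   (`status`, tuned configuration, averaged `metrics` table, `ibs`,
#'   `r2_ibs`, per-fold detail for K-fold) plus the plan, times and seed.
#'   Wall-clock timings are attached as the volatile attribute `timing`,
#'   which is excluded from [report_json()].
#' @export
benchmark_dtsurv <- function(formula, data, horizon, methods, times,
                             metric = c("brier", "ibs"),
                             plan = split_plan(), n_intervals = 2:10,
                             censoring = c("observed", "half", "full"),
                             search = c("grid", "random"), budget = NULL,
                             refit = c("train", "train_val"), seed = 1) {
  metric <- match.arg(metric)
  censoring <- match.arg(censoring)
  search <- match.arg(search)
  refit <- match.arg(refit)
  stopifnot(length(methods) >= 1, !is.null(names(methods)),
            all(vapply(methods, inherits, logical(1), "dtsurv_method")))
  data <- as.data.frame(data)

  set.seed(seed)
  split_seed <- sample.int(.Machine$integer.max - 1L, 1)
  method_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(methods) * max(1, plan$repeats) *
                               max(1, plan$k) + length(methods))
  seed_ctr <- 0L
  next_seed <- function() {
    seed_ctr <<- seed_ctr + 1L
    method_seeds[seed_ctr]
  }

  surv_parts <- function(df) {
    y <- stats::model.response(stats::model.frame(formula, df))
    list(time = as.numeric(y[, "time"]), event = as.numeric(y[, "status"]))
  }

  run_one <- function(method, train, val, test, mseed) {
    tuned <- NULL
    if (method$type %in% c("link", "engine")) {
      tuned <- tune_dtsurv(formula, train, val, horizon, method,
                           n_intervals = n_intervals, times = times,
                           metric = metric, censoring = censoring,
                           search = search, budget = budget, seed = mseed)
    }
    refit_data <- if (!is.null(val) && refit == "train_val")
      rbind(train, val) else train
    J <- if (is.null(tuned)) n_intervals[1] else tuned$best$n_intervals
    pars <- if (is.null(tuned)) list() else tuned$best$params
    risk <- fit_and_predict(method, formula, refit_data, test, times,
                            horizon, J, censoring, pars, mseed)
    tp <- surv_parts(test)
    sc <- evaluate_predictions(risk, times, tp$time, tp$event)
    list(tuned = if (is.null(tuned)) NULL else tuned$best,
         score = sc)
  }

  results <- list()
  timing <- numeric(length(methods))
  names(timing) <- names(methods)

  if (plan$scheme == "holdout") {
    assign <- make_splits(survdata_for_split(formula, data), plan,
                          seed = split_seed)
    train <- data[assign == "train", , drop = FALSE]
    val <- data[assign == "validation", , drop = FALSE]
    test <- data[assign == "test", , drop = FALSE]
    for (m in names(methods)) {
      t0 <- proc.time()[["elapsed"]]
      mseed <- next_seed()
      res <- tryCatch(run_one(methods[[m]], train, val, test, mseed),
                      error = function(e) e)
      timing[m] <- proc.time()[["elapsed"]] - t0
      results[[m]] <- if (inherits(res, "error")) {
        list(label = methods[[m]]$label, status = "failed",
             message = conditionMessage(res))
      } else {
        list(label = methods[[m]]$label, status = "ok",
             tuned = res$tuned, metrics = res$score$table,
             ibs = res$score$ibs, r2_ibs = res$score$r2_ibs,
             seed = mseed)
      }
    }
  } else {
    folds <- make_splits(survdata_for_split(formula, data), plan,
                         seed = split_seed)
    for (m in names(methods)) {
      t0 <- proc.time()[["elapsed"]]
      per_fold <- list()
      tuned_list <- list()
      err <- NULL
      for (r in seq_len(plan$repeats)) {
        for (f in seq_len(plan$k)) {
          mseed <- next_seed()
          test <- data[folds[, r] == f, , drop = FALSE]
          rest <- data[folds[, r] != f, , drop = FALSE]
          inner <- inner_split(formula, rest, val_frac = 0.25,
                               seed = mseed)
          res <- tryCatch(
            run_one(methods[[m]], rest[inner == "train", , drop = FALSE],
                    rest[inner == "validation", , drop = FALSE],
                    test, mseed),
            error = function(e) e)
          if (inherits(res, "error")) {
            err <- conditionMessage(res)
            next
          }
          # tuned on the inner split; refit on all remaining folds
          risk_refit <- fit_and_predict(
            methods[[m]], formula, rest, test, times, horizon,
            if (is.null(res$tuned)) n_intervals[1] else
              res$tuned$n_intervals,
            censoring,
            if (is.null(res$tuned)) list() else res$tuned$params, mseed)
          tp <- surv_parts(test)
          sc <- evaluate_predictions(risk_refit, times, tp$time, tp$event)
          per_fold[[length(per_fold) + 1L]] <-
            list(repeat_ = r, fold = f, tuned = res$tuned,
                 metrics = sc$table, ibs = sc$ibs, r2_ibs = sc$r2_ibs)
          tuned_list[[length(tuned_list) + 1L]] <- res$tuned
        }
      }
      timing[m] <- proc.time()[["elapsed"]] - t0
      results[[m]] <- if (length(per_fold) == 0L) {
        list(label = methods[[m]]$label, status = "failed", message = err)
      } else {
        avg <- Reduce(`+`, lapply(per_fold, function(z)
          as.matrix(z$metrics[, c("auc", "brier", "brier_null", "r2")]))) /
          length(per_fold)
        list(label = methods[[m]]$label, status = "ok",
             metrics = data.frame(time = times, avg),
             ibs = mean_or_null(lapply(per_fold, `[[`, "ibs")),
             r2_ibs = mean_or_null(lapply(per_fold, `[[`, "r2_ibs")),
             per_fold = per_fold, n_folds = length(per_fold))
      }
    }
  }

  out <- structure(list(results = results, plan = plan, times = times,
                        metric = metric, seed = seed,
                        n = nrow(data), horizon = horizon),
                   class = "dtsurv_benchmark")
  attr(out, "timing") <- timing
  out
}

mean_or_null <- function(lst) {
  v <- unlist(Filter(Negate(is.null), lst))
  if (length(v)) mean(v) else NULL
}

# survival_data view of the formula's time/event for stratified splitting
survdata_for_split <- function(formula, data) {
  y <- stats::model.response(stats::model.frame(formula, data))
  survival_data(data.frame(time = as.numeric(y[, "time"]),
                           event = as.numeric(y[, "status"]),
                           .x = 0),
                covariates = ".x")
}

# stratified two-way split used for inner tuning within CV folds
inner_split <- function(formula, data, val_frac, seed) {
  y <- stats::model.response(stats::model.frame(formula, data))
  strata <- as.integer(factor(as.numeric(y[, "status"])))
  counts <- alloc_counts(nrow(data), c(1 - val_frac, val_frac))
  stratified_assign(strata, counts, c("train", "validation"), seed)
}

#' @export
print.dtsurv_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark: %d methods, %s plan, n = %d, horizon = %g\n",
              length(x$results), x$plan$scheme, x$n, x$horizon))
  for (m in names(x$results)) {
    r <- x$results[[m]]
    if (r$status != "ok") {
      cat(sprintf("  %-16s FAILED: %s\n", r$label, r$message))
      next
    }
    line <- sprintf("  %-16s", r$label)
    if (!is.null(r$ibs)) {
      line <- paste0(line, sprintf(" IBS %.4f  R2_IBS %.4f", r$ibs,
                                   r$r2_ibs))
    } else {
      line <- paste0(line, sprintf(" BS(%g) %.4f  R2 %.4f",
                                   x$times[1], r$metrics$brier[1],
                                   r$metrics$r2[1]))
    }
    if (!is.null(r$tuned)) {
      line <- paste0(line, sprintf("  [J = %d]", r$tuned$n_intervals))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Canonical JSON serialization of a benchmark report
#'
#' Deterministic rendering of everything reproducible in the report: tuned
#' configurations, per-time metrics, integrated scores, seeds and the plan.
#' Volatile wall-clock timings are deliberately excluded, so identical runs
#' serialize byte-identically. Requires \pkg{jsonlite}.
#'
#' @param x a [benchmark_dtsurv()] report.
#' @param file optional path; when given the JSON is also written there.
#' @return the JSON string, invisibly when `file` is given.
#' @export
report_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "dtsurv_benchmark"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("report_json requires the 'jsonlite' package", call. = FALSE)
  }
  payload <- list(
    plan = unclass(x$plan), times = x$times, metric = x$metric,
    seed = x$seed, n = x$n, horizon = x$horizon,
    methods = lapply(x$results, function(r) {
      keep <- setdiff(names(r), "per_fold")
      out <- r[keep]
      if (!is.null(r$per_fold)) {
        out$per_fold <- lapply(r$per_fold, function(z)
          list(repeat_ = z$repeat_, fold = z$fold, tuned = z$tuned,
               metrics = z$metrics, ibs = z$ibs, r2_ibs = z$r2_ibs))
      }
      out
    }))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
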