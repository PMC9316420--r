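#' Kaplan-Meier step estimate of a survival function
#'
#' Product-limit estimate wrapped as a right-continuous step function, used
#' both for the marginal survival (the null prediction model) and, with
#' `flip_events = TRUE`, for the censoring distribution
#' \eqn{\hat G(u) = \Pr(C > u)} that drives the IPCW weights.
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicators.
#' @param flip_events estimate the censoring distribution by exchanging the
#'   roles of event and censoring.
#' @return an object of class `"surv_step"`: a list with `time`, `surv`,
#'   `fun` (right-continuous evaluator \eqn{S(t)}) and `fun_left` (left
#'   limit \eqn{S(t-)}).
#' @examples
#' km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$fun(2.5)  # 0.5
#' @export
km_curve <- function(time, event, flip_events = FALSE) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  if (flip_events) event <- 1 - event
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- sf$time
  ss <- sf$surv
  fun <- if (length(tt)) stats::stepfun(tt, c(1, ss), right = FALSE)
         else function(t) rep(1, length(t))
  fun_left <- if (length(tt)) stats::stepfun(tt, c(1, ss), right = TRUE)
              else function(t) rep(1, length(t))
  structure(list(time = tt, surv = ss, fun = fun, fun_left = fun_left),
            class = "surv_step")
}

#' @export
print.surv_step <- function(x, ...) {
  cat(sprintf("Step survival estimate: %d jump times, S(max) = %.4f\n",
              length(x$time), if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Inverse-probability-of-censoring weights at a time point
#'
#' Computes the IPCW weights \eqn{\hat W_i(t)} that recover the complete-
#' data contributions under right censoring: subjects still under follow-up
#' at \eqn{t} get \eqn{1/\hat G(t)}; subjects with an observed event by
#' \eqn{t} get \eqn{1/\hat G(\tilde T_i-)} (left limit, so a subject's own
#' censoring mass never enters its weight); subjects censored by \eqn{t} get
#' 0. Without censoring every weight is 1.
#'
#' @param t evaluation time.
#' @param time,event observed follow-up and event indicators of the
#'   evaluation data.
#' @param G optional censoring-distribution estimate ([km_curve()] with
#'   `flip_events = TRUE`), e.g. from a training split; defaults to
#'   estimating \eqn{\hat G} from `time`, `event` themselves.
#' @return numeric vector of weights.
#' @export
ipcw_weights <- function(t, time, event, G = NULL) {
  if (is.null(G)) G <- km_curve(time, event, flip_events = TRUE)
  stopifnot(inherits(G, "surv_step"))
  w <- numeric(length(time))
  at_risk <- time > t
  case <- time <= t & event == 1
  if (any(at_risk)) {
    g <- G$fun(t)
    if (g <= 0) {
      stop("censoring survival G(t) = 0 at t = ", signif(t, 6),
           "; evaluation beyond censoring support", call. = FALSE)
    }
    w[at_risk] <- 1 / g
  }
  if (any(case)) {
    g <- G$fun_left(time[case])
    if (any(g <= 0)) {
      bad <- time[case][g <= 0][1]
      stop("censoring survival G(t-) = 0 at t = ", signif(bad, 6),
           "; evaluation beyond censoring support", call. = FALSE)
    }
    w[case] <- 1 / g
  }
  w
}

#' IPCW time-dependent AUC (cumulative/dynamic)
#'
#' Estimates \eqn{AUC(t) = \Pr(p_i(t) > p_j(t) \mid T_i \le t, T_j > t)}:
#' the probability that a case (event by \eqn{t}) received a higher
#' predicted event probability than a control (still event-free at
#' \eqn{t}), with case/control contributions reweighted by [ipcw_weights()]
#' to account for censoring. Tied predictions contribute 0 by default (the
#' strict inequality); `ties = "half"` gives them half credit.
#'
#' @param t evaluation time.
#' @param risk predicted event probabilities \eqn{p_i(t) = 1 - S_i(t)}, one
#'   per subject.
#' @param time,event observed follow-up data.
#' @param G optional censoring-distribution estimate (see [ipcw_weights()]).
#' @param ties `"strict"` or `"half"`.
#' @return the estimated AUC in \eqn{[0, 1]}.
#' @export
td_auc <- function(t, risk, time, event, G = NULL,
                   ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(length(risk) == length(time))
  w <- ipcw_weights(t, time, event, G)
  status <- as.numeric(time <= t & event == 1)
  wi <- w * status          # case weights
  wj <- w * (1 - status)    # control weights (censored-by-t have w = 0)
  if (sum(wi) == 0 || sum(wj) == 0) {
    stop("time-dependent AUC undefined at t = ", signif(t, 6),
         ": no weighted ", if (sum(wi) == 0) "cases" else "controls",
         call. = FALSE)
  }
  ci <- which(wi > 0)
  cj <- which(wj > 0)
  cmp <- outer(risk[ci], risk[cj], ">") +
    if (ties == "half") 0.5 * outer(risk[ci], risk[cj], "==") else 0
  num <- sum(wi[ci] * (cmp %*% wj[cj]))
  den <- sum(wi[ci]) * sum(wj[cj])
  num / den
}

#' IPCW time-dependent Brier score
#'
#' Estimates the prediction error \eqn{BS(t) = E[(D(t) - p(t))^2]} with
#' \eqn{D(t) = I(T \le t)} via the censoring-weighted mean
#' \eqn{(1/n)\sum_i \hat W_i(t)\,(\tilde D_i(t) - p_i(t))^2}, where
#' \eqn{\tilde D_i(t) = I(\tilde T_i \le t, \delta_i = 1)}. Without
#' censoring this is the plain mean squared error of the predicted event
#' probabilities against the observed status.
#'
#' @inheritParams td_auc
#' @return the estimated Brier score in \eqn{[0, 1]}.
#' @export
td_brier <- function(t, risk, time, event, G = NULL) {
  stopifnot(length(risk) == length(time))
  w <- ipcw_weights(t, time, event, G)
  status <- as.numeric(time <= t & event == 1)
  mean(w * (status - risk)^2)
}

#' Null-model scaled R-squared of the Brier score
#'
#' \eqn{R^2(t) = 1 - BS(t)/BS_0(t)}, where \eqn{BS_0} is the Brier score of
#' the null model assigning every subject the marginal Kaplan-Meier event
#' probability. Positive values indicate predictive gain over the marginal
#' model; the measure may be negative.
#'
#' @param bs model Brier score.
#' @param bs_null null-model Brier score; must be positive.
#' @return \eqn{1 - bs/bs_{null}}.
#' @export
brier_r2 <- function(bs, bs_null) {
  if (any(bs_null <= 0)) {
    stop("null-model Brier score is 0; R-squared undefined", call. = FALSE)
  }
  1 - bs / bs_null
}

#' Integrated Brier score
#'
#' Integrates a Brier-score curve against the weight \eqn{W(t) = t/t^*},
#' i.e. \eqn{IBS = (1/t^*) \int_0^{t^*} BS(s)\,ds}, by the trapezoidal rule
#' over the evaluation grid, extending the curve as constant from the first
#' and last evaluated times to the ends of the range.
#'
#' @param times sorted evaluation times within \eqn{[0, t^*]} (at least 2).
#' @param bs Brier-score values at `times`.
#' @param t_star upper end of the integration range; defaults to
#'   `max(times)`.
#' @return the integrated Brier score.
#' @export
integrated_brier <- function(times, bs, t_star = max(times)) {
  stopifnot(length(times) == length(bs))
  if (length(times) < 2L) {
    stop("need at least two evaluation times to integrate", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE) || any(times < 0) ||
      any(times > t_star)) {
    stop("times must be strictly increasing within [0, t_star]",
         call. = FALSE)
  }
  tt <- c(0, times, t_star)
  yy <- c(bs[1], bs, bs[length(bs)])
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2) / t_star
}

#' Censoring-adjusted performance metrics for survival predictions
#'
#' Scores a matrix of predicted event probabilities against observed
#' right-censored outcomes: time-dependent AUC, Brier score, the null-model
#' (Kaplan-Meier) Brier score, \eqn{R^2(t) = 1 - BS/BS_0}, and the
#' integrated Brier score over \eqn{[0, t^*]} with its own \eqn{R^2}. The
#' scorer consumes only predictions, so discrete-time, continuous-time or
#' external models are evaluated identically.
#'
#' @param risk subjects x times matrix of predicted event probabilities
#'   \eqn{p_i(t)} (rows nondecreasing in \eqn{t}), or a vector when a single
#'   time is evaluated.
#' @param times evaluation times, one per column of `risk`.
#' @param time,event observed follow-up data for the scored subjects.
#' @param t_star upper end for the integrated Brier score; defaults to
#'   `max(times)`. The IBS is only computed when at least two times are
#'   evaluated.
#' @param G optional censoring-distribution estimate (see [ipcw_weights()]);
#'   default estimates \eqn{\hat G} on the evaluation data.
#' @param ties tie handling for the AUC; see [td_auc()].
#' @return an object of class `"dtsurv_score"`: a list with `table` (one
#'   row per time: `time`, `auc`, `brier`, `brier_null`, `r2`, `n_cases`,
#'   `n_controls`, `n_zero_weight`), `ibs`, `ibs_null`, `r2_ibs`, and the
#'   `weights` matrix used (times in columns), for audit.
#' @export
evaluate_predictions <- function(risk, times, time, event,
                                 t_star = max(times), G = NULL,
                                 ties = c("strict", "half")) {
  ties <- match.arg(ties)
  risk <- as.matrix(risk)
  if (ncol(risk) != length(times)) {
    stop("ncol(risk) must equal length(times)", call. = FALSE)
  }
  if (any(risk < 0) || any(risk > 1)) {
    stop("predicted event probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(G)) G <- km_curve(time, event, flip_events = TRUE)
  km <- km_curve(time, event)
  W <- matrix(NA_real_, nrow = length(time), ncol = length(times))
  tab <- data.frame(time = times, auc = NA_real_, brier = NA_real_,
                    brier_null = NA_real_, r2 = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    n_zero_weight = NA_integer_)
  for (k in seq_along(times)) {
    t <- times[k]
    w <- ipcw_weights(t, time, event, G)
    W[, k] <- w
    status <- as.numeric(time <= t & event == 1)
    p0 <- 1 - km$fun(t)
    tab$auc[k] <- td_auc(t, risk[, k], time, event, G, ties = ties)
    tab$brier[k] <- mean(w * (status - risk[, k])^2)
    tab$brier_null[k] <- mean(w * (status - p0)^2)
    tab$r2[k] <- brier_r2(tab$brier[k], tab$brier_null[k])
    tab$n_cases[k] <- sum(status == 1 & w > 0)
    tab$n_controls[k] <- sum(time > t)
    tab$n_zero_weight[k] <- sum(w == 0)
  }
  out <- list(table = tab, weights = W, t_star = t_star)
  if (length(times) >= 2L) {
    out$ibs <- integrated_brier(times, tab$brier, t_star)
    out$ibs_null <- integrated_brier(times, tab$brier_null, t_star)
    out$r2_ibs <- brier_r2(out$ibs, out$ibs_null)
  }
  class(out) <- "dtsurv_score"
  out
}

#' @export
print.dtsurv_score <- function(x, ...) {
  cat("Censoring-adjusted prediction metrics\n")
  print(cbind(x$table[, c("time", "auc", "brier", "brier_null", "r2")]),
        digits = 4, row.names = FALSE)
  if (!is.null(x$ibs)) {
    cat(sprintf("IBS = %.4f (null %.4f), R2_IBS = %.4f\n",
                x$ibs, x$ibs_null, x$r2_ibs))
  }
  invisible(x)
}

#' @export
plot.dtsurv_score <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$time, tab$brier, type = "b", ylim = c(0, max(
    tab$brier_null, tab$brier)), xlab = "time", ylab = "Brier score",
    main = "Prediction error curve", ...)
  graphics::lines(tab$time, tab$brier_null, type = "b", lty = 2, col = 2)
  graphics::legend("topleft", c("model", "null (Kaplan-Meier)"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Write a metrics table as tidy CSV
#'
#' Long format (`model`, `time`, `metric`, `value`) for downstream
#' inspection or plotting.
#'
#' @param x a `dtsurv_score`.
#' @param file output path.
#' @param model model label for the `model` column.
#' @return `file`, invisibly.
#' @export
write_metrics_csv <- function(x, file, model = "model") {
  stopifnot(inherits(x, "dtsurv_score"))
  tab <- x$table
  long <- do.call(rbind, lapply(c("auc", "brier", "brier_null", "r2"),
    function(m) data.frame(model = model, time = tab$time, metric = m,
                           value = tab[[m]])))
  if (!is.null(x$ibs)) {
    long <- rbind(long,
                  data.frame(model = model, time = NA_real_,
                             metric = c("ibs", "r2_ibs"),
                             value = c(x$ibs, x$r2_ibs)))
  }
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}
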