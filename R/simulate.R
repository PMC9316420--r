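#' Simulate right-censored survival data with known ground truth
#'
#' Draws event times from a parametric family with proportional covariate
#' effects on the hazard, applies independent censoring calibrated to a
#' target censoring proportion, and returns a [survival_data()] object that
#' additionally carries oracle access to the true conditional survival
#' function and the latent (uncensored) event times. Every other part of
#' the package is testable against this generator without external data.
#'
#' Families (all proportional hazards, linear predictor
#' \eqn{\eta = \beta'X} plus an optional threshold effect):
#' \describe{
#'   \item{`"exponential"`}{\eqn{h(t|x) = \lambda_0 e^\eta}; `base_rate` is
#'     \eqn{\lambda_0}.}
#'   \item{`"weibull_ph"`}{baseline cumulative hazard
#'     \eqn{H_0(t) = (t/scale)^{shape}}, so
#'     \eqn{S(t|x) = \exp\{-(t/scale)^{shape} e^\eta\}}.}
#'   \item{`"piecewise"`}{piecewise-constant baseline hazard with `rates`
#'     on the intervals defined by `breaks` (starting at 0, last piece
#'     extending to infinity).}
#'   \item{`"discrete"`}{a natively discrete generator: given an
#'     [interval_grid()] `grid` and baseline per-interval hazards
#'     `base_hazards`, the event interval is drawn by sequential Bernoulli
#'     trials with \eqn{\lambda_j(x) = 1-(1-\lambda_{0j})^{e^\eta}}
#'     (grouped proportional hazards); event times are the interval right
#'     endpoints and survivors past the grid are administratively censored
#'     at the horizon.}
#' }
#'
#' Censoring times are drawn independently of the event times given the
#' covariates. The censoring parameter (exponential rate, uniform upper
#' bound, or administrative cutoff) is calibrated by root finding so that
#' the expected censoring proportion, conditional on the realized event
#' times, equals `censor_rate`.
#'
#' @param n number of subjects.
#' @param family event-time family, see Details.
#' @param n_covariates number of independent standard-normal covariates.
#' @param n_binary number of additional independent Bernoulli(0.5)
#'   covariates.
#' @param beta covariate coefficients (length `n_covariates + n_binary`, or
#'   a scalar recycled).
#' @param threshold optional nonlinear scenario: a list
#'   `list(var = "x1", at = 0, effect = 1)` adding `effect * I(x > at)` to
#'   the linear predictor, a form a linear-in-covariates model cannot
#'   represent.
#' @param base_rate,shape,scale,breaks,rates,grid,base_hazards family
#'   parameters, see Details.
#' @param censoring censoring family.
#' @param censor_rate target censoring proportion in \eqn{[0, 1)}; 0 means
#'   no censoring.
#' @param seed integer seed; the draw is fully reproducible.
#' @return a `survival_data` object (columns `time`, `event`, `x1`, ...)
#'   with class `c("sim_surv", "survival_data", "data.frame")` and
#'   attributes `latent` (true event and censoring times) and `oracle`
#'   (generator parameters and the true survival function); query the
#'   oracle with [true_survival()] and [true_discrete_hazards()].
#' @examples
#' sim <- simulate_survival(500, family = "weibull_ph", beta = 0.7,
#'                          censoring = "exponential", censor_rate = 0.3,
#'                          seed = 42)
#' mean(sim$event == 0)  # close to 0.3
#' @export
simulate_survival <- function(n,
                              family = c("exponential", "weibull_ph",
                                         "piecewise", "discrete"),
                              n_covariates = 1, n_binary = 0, beta = 0.7,
                              threshold = NULL,
                              base_rate = 0.1, shape = 1.5, scale = 5,
                              breaks = NULL, rates = NULL,
                              grid = NULL, base_hazards = NULL,
                              censoring = c("none", "exponential",
                                            "uniform", "administrative"),
                              censor_rate = 0, seed = NULL) {
  family <- match.arg(family)
  censoring <- match.arg(censoring)
  stopifnot(n >= 1, censor_rate >= 0, censor_rate < 1)
  if (!is.null(seed)) set.seed(seed)

  p <- n_covariates + n_binary
  if (p < 1L) stop("need at least one covariate", call. = FALSE)
  beta <- rep_len(beta, p)
  X <- cbind(
    if (n_covariates > 0)
      matrix(stats::rnorm(n * n_covariates), n, n_covariates),
    if (n_binary > 0)
      matrix(stats::rbinom(n * n_binary, 1, 0.5), n, n_binary))
  colnames(X) <- paste0("x", seq_len(p))

  lin_pred <- function(X) {
    eta <- drop(X %*% beta)
    if (!is.null(threshold)) {
      eta <- eta + threshold$effect * (X[, threshold$var] > threshold$at)
    }
    eta
  }
  eta <- lin_pred(X)

  # baseline cumulative hazard and its inverse, per family
  if (family == "exponential") {
    H0 <- function(t) base_rate * t
    H0inv <- function(h) h / base_rate
  } else if (family == "weibull_ph") {
    H0 <- function(t) (t / scale)^shape
    H0inv <- function(h) scale * h^(1 / shape)
  } else if (family == "piecewise") {
    if (is.null(breaks) || is.null(rates) ||
        length(rates) != length(breaks)) {
      stop("piecewise family needs breaks (starting at 0) and one rate per piece",
           call. = FALSE)
    }
    if (breaks[1] != 0 || any(diff(breaks) <= 0) || any(rates <= 0)) {
      stop("breaks must start at 0 and increase; rates must be positive",
           call. = FALSE)
    }
    cumH <- c(0, cumsum(rates[-length(rates)] * diff(breaks)))
    H0 <- function(t) {
      k <- findInterval(t, breaks)
      cumH[k] + rates[k] * (t - breaks[k])
    }
    H0inv <- function(h) {
      k <- findInterval(h, cumH)
      breaks[k] + (h - cumH[k]) / rates[k]
    }
  }

  if (family == "discrete") {
    if (is.null(grid) || is.null(base_hazards) ||
        length(base_hazards) != grid$n_intervals) {
      stop("discrete family needs an interval_grid and one base hazard per interval",
           call. = FALSE)
    }
    stopifnot(all(base_hazards > 0), all(base_hazards < 1))
    lam <- 1 - outer(exp(eta), 1 - base_hazards, function(e, q) q^e)
    u <- matrix(stats::runif(n * grid$n_intervals), n)
    jfail <- apply(u < lam, 1L, function(z)
      if (any(z)) which(z)[1] else NA_integer_)
    T_true <- ifelse(is.na(jfail), Inf, grid$cut_points[-1L][jfail])
    surv_fun <- function(t, eta) {
      lam_x <- 1 - outer(exp(eta), 1 - base_hazards, function(e, q) q^e)
      k <- findInterval(t, grid$cut_points[-1L])
      logS <- cbind(0, t(apply(log1p(-lam_x), 1L, cumsum)))
      exp(logS[, k + 1L, drop = FALSE])
    }
  } else {
    T_true <- H0inv(stats::rexp(n) * exp(-eta))
    surv_fun <- function(t, eta) {
      exp(-outer(exp(eta), H0(t)))
    }
  }

  # censoring, calibrated so E[prop censored | realized T] = censor_rate
  C <- rep(Inf, n)
  cpar <- NA_real_
  if (censoring != "none" && censor_rate > 0) {
    if (censoring == "exponential") {
      f <- function(lc) mean(1 - exp(-lc * T_true)) - censor_rate
      cpar <- stats::uniroot(f, lower = 1e-10, upper = 1e6,
                             extendInt = "upX", tol = 1e-10)$root
      C <- stats::rexp(n, rate = cpar)
    } else if (censoring == "uniform") {
      f <- function(u) mean(pmin(T_true, u) / u) - censor_rate
      finiteT <- T_true[is.finite(T_true)]
      if (!length(finiteT)) stop("cannot censor: all event times infinite")
      cpar <- stats::uniroot(f, lower = min(finiteT) * 1e-6,
                             upper = max(finiteT) * 1e6, tol = 1e-10)$root
      C <- stats::runif(n, 0, cpar)
    } else { # administrative
      cpar <- as.numeric(stats::quantile(T_true, 1 - censor_rate,
                                         names = FALSE, type = 1))
      if (!is.finite(cpar) || cpar <= 0) {
        stop("administrative censoring target unattainable for these event times",
             call. = FALSE)
      }
      C <- rep(cpar, n)
    }
  }
  if (family == "discrete") C <- pmin(C, grid$horizon)

  time_obs <- pmin(T_true, C)
  event <- as.integer(T_true <= C)
  if (any(!is.finite(time_obs))) {
    stop("infinite follow-up times generated; add censoring or a horizon",
         call. = FALSE)
  }

  out <- survival_data(
    data.frame(time = time_obs, event = event, X, check.names = FALSE),
    time = "time", event = "event", covariates = colnames(X))
  class(out) <- c("sim_surv", class(out))
  attr(out, "latent") <- data.frame(event_time = T_true, censor_time = C)
  attr(out, "oracle") <- list(family = family, beta = beta,
                              threshold = threshold, lin_pred = lin_pred,
                              surv = surv_fun, censor_param = cpar)
  out
}

#' True conditional survival probabilities of a simulated data set
#'
#' Evaluates the generator's closed-form \eqn{S(t \mid x)} for oracle
#' checks.
#'
#' @param sim a [simulate_survival()] result.
#' @param t evaluation times.
#' @param newdata covariate data frame; defaults to the simulated subjects.
#' @return subjects x times matrix of survival probabilities.
#' @export
true_survival <- function(sim, t, newdata = NULL) {
  stopifnot(inherits(sim, "sim_surv"))
  orc <- attr(sim, "oracle")
  X <- if (is.null(newdata)) sd_covs(sim) else
    as.matrix(newdata[, attr(sim, "covariates"), drop = FALSE])
  S <- orc$surv(t, orc$lin_pred(X))
  dimnames(S) <- list(NULL, paste0("t=", signif(t, 6)))
  S
}

#' True per-interval discrete hazards of a simulated data set
#'
#' The discrete-time estimand implied by the continuous ground truth:
#' \eqn{\lambda_j(x) = \{S(t_{j-1}|x) - S(t_j|x)\} / S(t_{j-1}|x)}. By the
#' telescoping product, \eqn{\prod_{j: t_j \le t}(1-\lambda_j)} recovers
#' \eqn{S(t|x)} exactly at the grid points.
#'
#' @param sim a [simulate_survival()] result.
#' @param grid an [interval_grid()] within the generator support.
#' @param newdata covariate data frame; defaults to the simulated subjects.
#' @return subjects x intervals matrix of hazards.
#' @export
true_discrete_hazards <- function(sim, grid, newdata = NULL) {
  stopifnot(inherits(grid, "interval_grid"))
  S_lo <- true_survival(sim, grid$cut_points[-(grid$n_intervals + 1L)],
                        newdata)
  S_hi <- true_survival(sim, grid$cut_points[-1L], newdata)
  if (any(S_lo == 0)) {
    stop("true survival is 0 at an interval start; hazard undefined",
         call. = FALSE)
  }
  lam <- (S_lo - S_hi) / S_lo
  colnames(lam) <- paste0("A", seq_len(grid$n_intervals))
  lam
}

#' Write a simulated data set to CSV with a parameter sidecar
#'
#' @param sim a [simulate_survival()] result.
#' @param file CSV output path; a JSON sidecar `<file>.json` records the
#'   generating family, coefficients and censoring parameter (requires
#'   \pkg{jsonlite}).
#' @return `file`, invisibly.
#' @export
write_simulation <- function(sim, file) {
  stopifnot(inherits(sim, "sim_surv"))
  utils::write.csv(as.data.frame(sim), file, row.names = FALSE)
  orc <- attr(sim, "oracle")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(family = orc$family, beta = orc$beta,
           censor_param = orc$censor_param, n = nrow(sim)),
      paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
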