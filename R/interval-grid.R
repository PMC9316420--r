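#' Interval grid for discretizing follow-up time
#'
#' A grid of cut points \eqn{t_0 = 0 < t_1 < \dots < t_J = w} partitioning
#' the follow-up range into \eqn{J} left-open right-closed intervals
#' \eqn{A_j = (t_{j-1}, t_j]}. The convention is fixed: an event at exactly
#' \eqn{t_j} falls in \eqn{A_j}.
#'
#' @param cut_points strictly increasing numeric vector starting at 0.
#' @return an object of class `"interval_grid"` with elements `cut_points`,
#'   `horizon` (\eqn{t_J}) and `n_intervals` (\eqn{J}).
#' @seealso [quantile_grid()] for the data-driven constructor.
#' @examples
#' interval_grid(0:5)
#' @export
interval_grid <- function(cut_points) {
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) < 2L) stop("need at least two cut points")
  if (cut_points[1] != 0) stop("first cut point must be exactly 0")
  if (any(diff(cut_points) <= 0)) {
    stop("cut points must be strictly increasing")
  }
  structure(list(cut_points = cut_points,
                 horizon = cut_points[length(cut_points)],
                 n_intervals = length(cut_points) - 1L),
            class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("Interval grid: J = %d intervals on (0, %g]\n",
              x$n_intervals, x$horizon))
  cat("  cut points:", paste(signif(x$cut_points, 5), collapse = " "), "\n")
  invisible(x)
}

#' Event-time-quantile interval grid
#'
#' Builds an interval grid whose interior cut points are the
#' \eqn{1/J, \dots, (J-1)/J} empirical quantiles of the observed event times
#' within the horizon (subjects with \eqn{\delta = 1, \tilde T \le w}), with
#' \eqn{t_0 = 0} and \eqn{t_J = w} forced. Each interval then holds an
#' approximately equal share of the in-horizon events, so every interval has
#' failures to inform its hazard. Quantiles interpolate the empirical CDF
#' linearly (`stats::quantile` type 4), so with event times \eqn{1,\dots,5},
#' horizon 5 and \eqn{J = 5} the grid is the unit grid \eqn{0,1,\dots,5}.
#'
#' Tied event times can make quantiles coincide; duplicated cut points are
#' collapsed with a warning and the realized grid has fewer intervals than
#' requested.
#'
#' @param x a [survival_data()] object.
#' @param horizon positive prediction horizon \eqn{w}.
#' @param n_intervals requested number of intervals \eqn{J \ge 1}.
#' @return an [interval_grid()]; its `n_intervals` is the realized count.
#' @examples
#' d <- survival_data(data.frame(time = 1:5, event = rep(1, 5)))
#' quantile_grid(d, horizon = 5, n_intervals = 5)
#' @export
quantile_grid <- function(x, horizon, n_intervals) {
  stopifnot(inherits(x, "survival_data"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be a single positive number", call. = FALSE)
  }
  if (n_intervals < 1L) stop("n_intervals must be >= 1", call. = FALSE)
  et <- sd_time(x)[sd_event(x) == 1 & sd_time(x) <= horizon]
  if (length(et) == 0L) {
    stop("no events observed within the horizon; grid cannot be fit",
         call. = FALSE)
  }
  interior <- if (n_intervals > 1L) {
    as.numeric(stats::quantile(et, probs = seq_len(n_intervals - 1L) /
                                 n_intervals, type = 4, names = FALSE))
  } else numeric(0)
  interior <- interior[interior > 0 & interior < horizon]
  cuts <- unique(c(0, interior, horizon))
  if (length(cuts) < n_intervals + 1L) {
    warning(sprintf(
      "tied event-time quantiles: realized grid has %d intervals (%d requested)",
      length(cuts) - 1L, n_intervals), call. = FALSE)
  }
  interval_grid(cuts)
}

#' Map a time to its interval index
#'
#' Returns the unique \eqn{j} with \eqn{t_{j-1} < t \le t_j} under the
#' left-open right-closed convention; a time exactly at a cut point belongs
#' to the interval ending there.
#'
#' @param t numeric times in \eqn{(0, w]}.
#' @param grid an [interval_grid()].
#' @return integer interval indices, same length as `t`.
#' @examples
#' g <- interval_grid(0:5)
#' interval_index(c(2.5, 3), g)  # 3 3
#' @export
interval_index <- function(t, grid) {
  stopifnot(inherits(grid, "interval_grid"))
  if (any(t <= 0) || any(t > grid$horizon)) {
    stop("times must lie in (0, horizon]", call. = FALSE)
  }
  findInterval(t, grid$cut_points, left.open = TRUE)
}
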