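#' Expand survival data to a person-period table
#'
#' Converts one-row-per-subject survival data into the long person-period
#' format on which discrete hazard models are fit: subjects contribute one
#' row per interval at which they are at risk, with a binary event-history
#' indicator `d` that is 1 only in the interval where the event occurs.
#' Per subject the `d` sequence is therefore \eqn{(0,\dots,0)} (censored) or
#' \eqn{(0,\dots,0,1)} (event), and the binomial likelihood of the rows
#' equals the discrete-time survival likelihood.
#'
#' An event subject with event time in interval \eqn{A_{j_i}} contributes
#' rows \eqn{1,\dots,j_i} under every censoring specification. For censored
#' subjects, `censoring` selects which intervals count as survived:
#' \describe{
#'   \item{`"observed"`}{every interval the subject enters, i.e. all \eqn{j}
#'     with \eqn{t_{j-1} < \tilde T} (at risk at the start of the interval).}
#'   \item{`"half"`}{intervals of which at least half is survived:
#'     \eqn{\tilde T \ge (t_{j-1}+t_j)/2}.}
#'   \item{`"full"`}{only fully survived intervals: \eqn{\tilde T \ge t_j}
#'     (censoring treated as occurring at the end of the previous interval,
#'     as in discrete data collection by scheduled visits).}
#' }
#' A censored subject whose rule yields zero intervals contributes no rows;
#' such subjects are counted in attribute `dropped` rather than erroring.
#'
#' @param x a [survival_data()] object. If any follow-up exceeds
#'   `grid$horizon`, administrative censoring at the horizon is applied
#'   first.
#' @param grid an [interval_grid()].
#' @param censoring censoring specification for censored subjects; one of
#'   `"observed"`, `"half"`, `"full"`.
#' @return a data frame of class `"person_period"` with columns `id`,
#'   `interval` (integer index), `interval_label` (factor `A1..AJ`), `t_lo`,
#'   `t_hi`, the covariates, and `d`. Attributes: `grid`, `censoring`,
#'   `covariates`, `dropped` (ids contributing zero rows).
#' @examples
#' d <- survival_data(data.frame(time = c(2.5, 3.1, 6), event = c(1, 0, 1)))
#' person_period(d, interval_grid(0:5))
#' @export
person_period <- function(x, grid,
                          censoring = c("observed", "half", "full")) {
  stopifnot(inherits(x, "survival_data"), inherits(grid, "interval_grid"))
  censoring <- match.arg(censoring)
  if (any(sd_time(x) > grid$horizon)) x <- admin_censor(x, grid$horizon)

  time <- sd_time(x)
  event <- sd_event(x)
  J <- grid$n_intervals
  lo <- grid$cut_points[-(J + 1L)]
  hi <- grid$cut_points[-1L]
  mid <- (lo + hi) / 2

  # number of rows contributed per subject
  n_rows <- integer(nrow(x))
  is_ev <- event == 1
  n_rows[is_ev] <- interval_index(time[is_ev], grid)
  cz <- !is_ev
  n_rows[cz] <- switch(censoring,
    observed = vapply(time[cz], function(tt) sum(lo < tt), integer(1)),
    half     = vapply(time[cz], function(tt) sum(tt >= mid), integer(1)),
    full     = vapply(time[cz], function(tt) sum(tt >= hi), integer(1)))

  dropped <- sd_id(x)[n_rows == 0L]
  keep <- n_rows > 0L
  idx <- rep(which(keep), n_rows[keep])
  j <- sequence(n_rows[keep])
  d <- integer(length(j))
  # terminal 1 for event subjects
  last <- cumsum(n_rows[keep])
  d[last[event[keep] == 1]] <- 1L

  covs <- attr(x, "covariates")
  out <- data.frame(id = sd_id(x)[idx],
                    interval = j,
                    interval_label = factor(sprintf("A%d", j),
                                            levels = paste0("A", seq_len(J))),
                    t_lo = lo[j], t_hi = hi[j],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(x)[idx, covs, drop = FALSE])
  out$d <- d
  rownames(out) <- NULL
  structure(out, class = c("person_period", "data.frame"),
            grid = grid, censoring = censoring, covariates = covs,
            dropped = dropped)
}

#' @export
print.person_period <- function(x, n = 6L, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "Person-period table: %d rows, %d subjects, J = %d, censoring = '%s'\n",
    nrow(x), length(unique(x$id)), g$n_intervals, attr(x, "censoring")))
  if (length(attr(x, "dropped"))) {
    cat("  dropped subjects (zero rows):", length(attr(x, "dropped")), "\n")
  }
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Person-period layout for prediction
#'
#' Expands prediction subjects to exactly \eqn{J} rows each (one per grid
#' interval, no event column) so a fitted hazard model can predict the
#' conditional failure probability for every interval.
#'
#' @param newdata data frame of covariates conforming to the training schema.
#' @param grid an [interval_grid()].
#' @param covariates covariate column names expected by the model.
#' @return a `person_period`-shaped data frame with `n * J` rows, columns
#'   `id` (row index into `newdata`), `interval`, `interval_label`, `t_lo`,
#'   `t_hi` and the covariates.
#' @export
expand_prediction <- function(newdata, grid, covariates = names(newdata)) {
  stopifnot(inherits(grid, "interval_grid"))
  missing_cols <- setdiff(covariates, names(newdata))
  if (length(missing_cols)) {
    stop("newdata is missing covariates: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(newdata)
  J <- grid$n_intervals
  idx <- rep(seq_len(n), each = J)
  j <- rep(seq_len(J), times = n)
  out <- data.frame(id = idx, interval = j,
                    interval_label = factor(sprintf("A%d", j),
                                            levels = paste0("A", seq_len(J))),
                    t_lo = grid$cut_points[j], t_hi = grid$cut_points[j + 1L])
  out <- cbind(out, newdata[idx, covariates, drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("person_period", "data.frame"),
            grid = grid, covariates = covariates, censoring = NA_character_,
            dropped = character(0))
}

#' Export a person-period table to CSV
#'
#' @param x a [person_period()] table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_person_period <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
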