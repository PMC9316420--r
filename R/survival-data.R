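#' Subject-level right-censored survival data
#'
#' Validates a one-row-per-subject data frame of right-censored follow-up and
#' marks which columns play the roles of follow-up time, event indicator,
#' subject identifier and baseline covariates. All downstream machinery
#' (interval grids, person-period expansion, model fitting, metrics) consumes
#' this container.
#'
#' The observed data for subject \eqn{i} are \eqn{(\tilde T_i, \delta_i, X_i)}
#' where \eqn{\tilde T_i = \min(T_i, C_i)} is the follow-up time,
#' \eqn{\delta_i = I(T_i \le C_i)} the event indicator and \eqn{X_i} the
#' baseline covariate vector. Covariates must be complete and numeric
#' (categorical covariates are one-hot encoded at load time, see
#' [read_survival_csv()]); missing-data handling is out of scope and rejected
#' here.
#'
#' @param data a data frame, one row per subject.
#' @param time name of the nonnegative follow-up time column.
#' @param event name of the 0/1 event indicator column.
#' @param id optional name of a unique subject identifier column; if `NULL`
#'   row numbers are used.
#' @param covariates character vector of covariate column names; defaults to
#'   every column other than time/event/id.
#'
#' @return the data frame with class `"survival_data"` and attributes
#'   `time`, `event`, `id`, `covariates` recording the column roles.
#' @examples
#' d <- survival_data(data.frame(time = c(2.5, 4, 1), status = c(1, 0, 1),
#'                               age = c(50, 61, 47)),
#'                    time = "time", event = "status")
#' @export
survival_data <- function(data, time = "time", event = "event", id = NULL,
                          covariates = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  for (col in c(time, event, id)) {
    if (!is.null(col) && !col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  tt <- data[[time]]
  ev <- data[[event]]
  if (anyNA(tt) || anyNA(ev)) {
    stop("missing values in time or event column; complete cases required",
         call. = FALSE)
  }
  if (!is.numeric(tt) || any(tt < 0)) {
    stop("followup time must be numeric and nonnegative", call. = FALSE)
  }
  if (!all(ev %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  # an event at exactly t = 0 cannot be placed in any left-open interval
  if (any(tt == 0 & ev == 1)) {
    stop("event at time 0 cannot be assigned to a left-open interval; ",
         "remove or correct these subjects", call. = FALSE)
  }
  if (is.null(id)) {
    data[[".id"]] <- seq_len(nrow(data))
    id <- ".id"
  }
  if (anyDuplicated(data[[id]])) {
    stop("subject ids must be unique", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(time, event, id))
  }
  for (v in covariates) {
    if (anyNA(data[[v]])) {
      stop("missing values in covariate '", v,
           "'; complete cases required", call. = FALSE)
    }
    if (!is.numeric(data[[v]])) {
      stop("covariate '", v, "' is not numeric; encode categorical ",
           "covariates first (see read_survival_csv)", call. = FALSE)
    }
  }
  structure(data, class = c("survival_data", "data.frame"),
            time = time, event = event, id = id, covariates = covariates)
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("Survival data: %d subjects, %d covariates, %.1f%% events\n",
              nrow(x), length(attr(x, "covariates")),
              100 * mean(x[[attr(x, "event")]])))
  cat("  time: ", attr(x, "time"), "  event: ", attr(x, "event"),
      "  id: ", attr(x, "id"), "\n", sep = "")
  invisible(x)
}

sd_time  <- function(x) x[[attr(x, "time")]]
sd_event <- function(x) x[[attr(x, "event")]]
sd_id    <- function(x) x[[attr(x, "id")]]
sd_covs  <- function(x) as.matrix(x[, attr(x, "covariates"), drop = FALSE])

# rebuild the survival_data class after row subsetting
sd_subset <- function(x, i) {
  survival_data(as.data.frame(x)[i, , drop = FALSE],
                time = attr(x, "time"), event = attr(x, "event"),
                id = attr(x, "id"), covariates = attr(x, "covariates"))
}

#' Read subject-level survival data from CSV
#'
#' Reads a delimited file, maps columns onto the time/event/covariate roles,
#' one-hot encodes declared categorical covariates with a persisted level
#' vocabulary, and validates via [survival_data()].
#'
#' @param file path to a CSV file with a header row.
#' @param time,event,id column names, as in [survival_data()].
#' @param covariates covariate columns; default all remaining columns.
#' @param categorical character vector naming covariate columns to one-hot
#'   encode. Each level `L` of column `v` becomes a 0/1 column `v.L`; the
#'   level sets are stored in attribute `vocabulary`.
#' @return a [survival_data()] object with attribute `vocabulary` (named list
#'   of factor levels used for encoding).
#' @export
read_survival_csv <- function(file, time = "time", event = "event",
                              id = NULL, covariates = NULL,
                              categorical = character()) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(covariates)) {
    covariates <- setdiff(names(raw), c(time, event, id))
  }
  vocab <- list()
  for (v in categorical) {
    if (!v %in% covariates) stop("categorical column '", v, "' not a covariate")
    f <- factor(raw[[v]])
    vocab[[v]] <- levels(f)
    mm <- stats::model.matrix(~ f - 1)
    colnames(mm) <- paste(v, levels(f), sep = ".")
    raw[[v]] <- NULL
    raw <- cbind(raw, as.data.frame(mm))
    covariates <- c(setdiff(covariates, v), colnames(mm))
  }
  out <- survival_data(raw, time = time, event = event, id = id,
                       covariates = covariates)
  attr(out, "vocabulary") <- vocab
  out
}

#' Administrative censoring at a prediction horizon
#'
#' Subjects with follow-up beyond `horizon` are treated as event-free at the
#' horizon: their follow-up time is set to `horizon` and their event
#' indicator to 0. This bounds the person-period expansion at the horizon of
#' interest. The input is not modified.
#'
#' @param x a [survival_data()] object.
#' @param horizon positive prediction horizon.
#' @return a new `survival_data` object.
#' @examples
#' d <- survival_data(data.frame(time = c(7.2, 3), event = c(1, 1)))
#' admin_censor(d, 5)  # first subject becomes (5, 0)
#' @export
admin_censor <- function(x, horizon) {
  stopifnot(inherits(x, "survival_data"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("horizon must be a single positive number", call. = FALSE)
  }
  out <- x
  beyond <- sd_time(x) > horizon
  out[[attr(x, "time")]][beyond] <- horizon
  out[[attr(x, "event")]][beyond] <- 0
  out
}
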