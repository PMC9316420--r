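test_that("subject-level validation rejects malformed data", {
  expect_error(survival_data(data.frame(time = c(1, -2), event = c(1, 0))),
               "nonnegative")
  expect_error(survival_data(data.frame(time = c(1, 2), event = c(1, 2))),
               "0/1")
  expect_error(survival_data(data.frame(time = c(0, 2), event = c(1, 0))),
               "time 0")
  expect_error(survival_data(data.frame(time = c(1, NA), event = c(1, 0))),
               "missing")
  expect_error(survival_data(data.frame(id = c(1, 1), time = c(1, 2),
                                        event = c(1, 0)), id = "id"),
               "unique")
  expect_error(survival_data(data.frame(time = 1:2, event = c(1, 0),
                                        x = c(3, NA))),
               "missing")
  # censored at exactly 0 is allowed (it is droppable, not invalid)
  expect_s3_class(survival_data(data.frame(time = c(0, 1),
                                           event = c(0, 1))),
                  "survival_data")
})

test_that("CSV reader maps columns and one-hot encodes with a vocabulary", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(t = c(1, 2, 3), ev = c(1, 0, 1), age = c(50, 60, 70),
                       sex = c("m", "f", "m")), f, row.names = FALSE)
  d <- read_survival_csv(f, time = "t", event = "ev", categorical = "sex")
  expect_setequal(attr(d, "covariates"), c("age", "sex.f", "sex.m"))
  expect_equal(d$sex.m, c(1, 0, 1))
  expect_equal(attr(d, "vocabulary")$sex, c("f", "m"))
  unlink(f)
})

test_that("administrative censoring truncates at the horizon without mutation", {
  d <- survival_data(data.frame(time = c(7.2, 3, 5), event = c(1, 1, 1)))
  out <- admin_censor(d, 5)
  expect_equal(sd_time <- out$time, c(5, 3, 5))
  expect_equal(out$event, c(0, 1, 1))
  expect_equal(d$time, c(7.2, 3, 5))  # input unchanged
  # property: no follow-up nor event beyond the horizon
  set.seed(11)
  r <- survival_data(data.frame(time = rexp(200, 0.3),
                                event = rbinom(200, 1, 0.7) ))
  rc <- admin_censor(r, 2)
  expect_true(all(rc$time <= 2))
  expect_true(all(rc$event[rc$time == 2 & r$time > 2] == 0))
  expect_error(admin_censor(d, -1), "positive")
})

test_that("quantile grid reproduces the unit-interval worked example", {
  d <- survival_data(data.frame(time = 1:5, event = rep(1, 5)))
  g <- quantile_grid(d, horizon = 5, n_intervals = 5)
  expect_equal(g$cut_points, as.numeric(0:5))
  expect_equal(g$n_intervals, 5L)
  # single-interval grid
  g1 <- quantile_grid(d, horizon = 5, n_intervals = 1)
  expect_equal(g1$cut_points, c(0, 5))
  expect_error(quantile_grid(d, horizon = -2, n_intervals = 3), "positive")
  dc <- survival_data(data.frame(time = c(6, 7), event = c(1, 1)))
  expect_error(quantile_grid(dc, horizon = 5, n_intervals = 3),
               "no events")
})

test_that("quantile grid balances in-horizon events across intervals", {
  set.seed(42)
  tt <- rexp(200, rate = 0.4)
  d <- survival_data(data.frame(time = tt, event = rep(1, 200)))
  horizon <- as.numeric(quantile(tt, 0.9))
  g <- quantile_grid(d, horizon, n_intervals = 10)
  in_h <- sort(tt[tt <= horizon])
  counts <- table(cut(in_h, g$cut_points))
  # sort-and-slice oracle: equal blocks of the sorted event times
  expect_true(all(abs(counts - length(in_h) / 10) <= 1))
})

test_that("tied event times collapse duplicate cut points with a warning", {
  d <- survival_data(data.frame(time = c(rep(1, 50), 5), event = rep(1, 51)))
  expect_warning(g <- quantile_grid(d, horizon = 5, n_intervals = 10),
                 "tied")
  expect_lt(g$n_intervals, 10)
  expect_equal(g$cut_points[1], 0)
  expect_equal(g$horizon, 5)
})

test_that("interval_index follows the left-open right-closed convention", {
  g <- unit_grid5()
  expect_equal(interval_index(2.5, g), 3L)        # event between 2 and 3
  expect_equal(interval_index(c(1, 2, 5), g), c(1L, 2L, 5L))  # boundaries
  expect_error(interval_index(0, g), "0, horizon")
  expect_error(interval_index(5.1, g), "0, horizon")
  # linear-scan oracle on an uneven grid
  g2 <- interval_grid(c(0, 0.3, 1.7, 2, 8.5))
  set.seed(7)
  tt <- runif(1000, min = 1e-9, max = 8.5)
  scan <- vapply(tt, function(t) {
    for (j in seq_len(g2$n_intervals)) {
      if (g2$cut_points[j] < t && t <= g2$cut_points[j + 1]) return(j)
    }
    NA_integer_
  }, integer(1))
  expect_equal(interval_index(tt, g2), scan)
})

test_that("expansion reproduces the worked person-period example", {
  pp <- person_period(worked_example_data(), unit_grid5())
  r1 <- pp[pp$id == 1, ]
  expect_equal(nrow(r1), 3L)
  expect_equal(r1$d, c(0L, 0L, 1L))
  r2 <- pp[pp$id == 2, ]
  expect_equal(nrow(r2), 4L)
  expect_equal(r2$d, rep(0L, 4))
  r3 <- pp[pp$id == 3, ]          # administratively censored at w = 5
  expect_equal(nrow(r3), 5L)
  expect_equal(r3$d, rep(0L, 5))
  # covariates copied unchanged onto every row
  expect_true(all(r1$x == 0.2))
  expect_equal(r1$interval, 1:3)
})

test_that("censoring specifications follow the half/full interval rules", {
  g <- unit_grid5()
  d <- survival_data(data.frame(id = 4:5, time = c(2.2, 3.7),
                                event = c(0, 0), x = c(0, 0)), id = "id")
  n_rows <- function(mode) {
    pp <- person_period(d, g, censoring = mode)
    c(sum(pp$id == 4), sum(pp$id == 5))
  }
  expect_equal(n_rows("observed"), c(3L, 4L))
  # censored in the first half of interval 3: drops that interval
  # censored in the second half of interval 4: kept under half, not full
  expect_equal(n_rows("half"), c(2L, 4L))
  expect_equal(n_rows("full"), c(2L, 3L))
})

test_that("a censored subject at exactly a cut point keeps that interval under all specs", {
  g <- unit_grid5()
  d <- survival_data(data.frame(time = 3, event = 0, x = 1))
  for (mode in c("observed", "half", "full")) {
    expect_equal(nrow(person_period(d, g, mode)), 3L, info = mode)
  }
})

test_that("zero-row subjects are dropped and logged, not errored", {
  g <- unit_grid5()
  d <- survival_data(data.frame(id = c("a", "b"), time = c(0, 0.2),
                                event = c(0, 0), x = 1:2), id = "id")
  pp <- person_period(d, g, censoring = "full")
  expect_equal(nrow(pp), 0L)
  expect_setequal(attr(pp, "dropped"), c("a", "b"))
  pp2 <- person_period(d, g, censoring = "observed")
  expect_equal(attr(pp2, "dropped"), "a")
  expect_equal(pp2$id, "b")
})

test_that("expansion invariants hold on random data", {
  set.seed(99)
  n <- 300
  d <- survival_data(data.frame(time = rexp(n, 0.25) + 0.01,
                                event = rbinom(n, 1, 0.6),
                                x1 = rnorm(n)))
  g <- interval_grid(c(0, 1.1, 2.5, 4, 7))
  dc <- admin_censor(d, g$horizon)
  pps <- lapply(c("observed", "half", "full"), function(m)
    person_period(dc, g, m))
  names(pps) <- c("observed", "half", "full")

  # row-count identity under observed_any vs the per-subject loop oracle
  oracle <- oracle_expand_rows(dc$time, dc$event, g$cut_points, "observed")
  expect_equal(nrow(pps$observed), sum(oracle))
  # and equality with sum of interval indices
  expect_equal(sum(oracle), sum(interval_index(pmax(dc$time, 1e-12), g)))

  for (m in names(pps)) {
    expect_equal(as.vector(table(factor(pps[[m]]$id, levels = seq_len(n)))) +
                   0L,
                 oracle_expand_rows(dc$time, dc$event, g$cut_points, m),
                 info = m)
    # d-pattern: all zeros or zeros then a single terminal 1
    for (pat in split(pps[[m]]$d, pps[[m]]$id)) {
      expect_true(sum(pat) <= 1)
      if (sum(pat) == 1) expect_equal(which(pat == 1), length(pat))
    }
    # contiguous interval prefix per subject
    for (iv in split(pps[[m]]$interval, pps[[m]]$id)) {
      expect_equal(iv, seq_along(iv))
    }
  }

  # monotonicity of censored-subject rows across specs
  cz <- dc$event == 0
  rows_by <- function(m) oracle_expand_rows(dc$time, dc$event,
                                            g$cut_points, m)[cz]
  expect_true(all(rows_by("full") <= rows_by("half")))
  expect_true(all(rows_by("half") <= rows_by("observed")))

  # event subjects identical under all specs
  ev_rows <- function(pp) {
    r <- as.data.frame(pp)[pp$id %in% which(!cz), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(ev_rows(pps$observed), ev_rows(pps$half),
               ignore_attr = TRUE)
  expect_equal(ev_rows(pps$observed), ev_rows(pps$full),
               ignore_attr = TRUE)

  # determinism: identical inputs give identical tables
  expect_identical(person_period(dc, g, "half"), pps$half)
})

test_that("prediction expansion yields J rows per subject with matching labels", {
  g <- unit_grid5()
  nd <- data.frame(x = c(0.5, -0.5, 2))
  pe <- expand_prediction(nd, g, covariates = "x")
  expect_equal(nrow(pe), 15L)
  expect_equal(pe$interval[pe$id == 1], 1:5)
  # label vocabulary identical to the training table's
  pp <- person_period(worked_example_data(), g)
  expect_identical(levels(pe$interval_label), levels(pp$interval_label))
  expect_error(expand_prediction(data.frame(y = 1), g, covariates = "x"),
               "missing covariates")
})

test_that("person-period tables export to CSV with interval endpoints", {
  f <- tempfile(fileext = ".csv")
  pp <- person_period(worked_example_data(), unit_grid5())
  write_person_period(pp, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(pp))
  expect_true(all(c("id", "interval", "t_lo", "t_hi", "x", "d") %in%
                    names(back)))
  expect_equal(back$t_hi - back$t_lo, rep(1, nrow(pp)))
  unlink(f)
})
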