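test_that("intercept-only fit reproduces the life table", {
  set.seed(3)
  n <- 120
  d <- data.frame(time = sample(1:5, n, replace = TRUE) - runif(n, 0, 0.5),
                  event = 1)
  g <- unit_grid5()
  fit <- dtsurv(survival::Surv(time, event) ~ 1, d, grid = g)
  lam <- predict(fit, data.frame(z = 1), type = "hazard")
  lt <- oracle_life_table(d$time, d$event, g)
  expect_equal(as.numeric(lam), lt, tolerance = 1e-6)
  # composed survival equals the empirical survival proportion at cut points
  S <- predict(fit, data.frame(z = 1), times = 1:5)
  emp <- vapply(1:5, function(t) mean(d$time > t), numeric(1))
  expect_equal(as.numeric(S), emp, tolerance = 1e-6)
})

test_that("logit link recovers the 2x2-table log odds ratio for a binary covariate", {
  # identical per-interval 2x2 tables: the pooled conditional log odds
  # ratio equals the single-table value exactly
  make_arm <- function(x, n_fail, n_surv, interval) {
    data.frame(interval = interval, x = x,
               d = rep(c(1L, 0L), c(n_fail, n_surv)))
  }
  rows <- rbind(make_arm(1, 20, 30, 1), make_arm(0, 10, 40, 1),
                make_arm(1, 20, 30, 2), make_arm(0, 10, 40, 2))
  pp <- data.frame(id = seq_len(nrow(rows)), interval = rows$interval,
                   interval_label = factor(paste0("A", rows$interval),
                                           levels = c("A1", "A2")),
                   t_lo = rows$interval - 1, t_hi = rows$interval,
                   x = rows$x, d = rows$d)
  attr(pp, "grid") <- interval_grid(0:2)
  class(pp) <- c("person_period", "data.frame")
  fit <- dtsurv:::fit_link_glm(pp, "x", "logit")
  lor <- log((20 / 30) / (10 / 40))
  expect_equal(unname(coef(fit)["x"]), lor, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["A1"]), unname(coef(fit)["A2"]),
               tolerance = 1e-6)
})

test_that("cloglog link estimates the proportional-hazards coefficient", {
  sim <- simulate_survival(1500, family = "weibull_ph", beta = 0.7,
                           shape = 1.3, scale = 6, seed = 202)
  fit <- dtsurv(surv_formula, sim, horizon = quantile(sim$time, 0.9),
                n_intervals = 12, link = "cloglog")
  expect_lt(abs(unname(coef(fit)["x1"]) - 0.7), 0.12)
})

test_that("logit and cloglog links nearly agree when hazards are small", {
  sim <- simulate_survival(2000, family = "exponential", beta = 0.4,
                           base_rate = 0.02, seed = 77)
  h <- 2.5  # short horizon so every per-interval hazard is small
  fl <- dtsurv(surv_formula, sim, horizon = h, n_intervals = 5,
               link = "logit")
  fc <- dtsurv(surv_formula, sim, horizon = h, n_intervals = 5,
               link = "cloglog")
  nd <- data.frame(x1 = c(-1, 0, 1))
  hl <- predict(fl, nd, type = "hazard")
  hc <- predict(fc, nd, type = "hazard")
  expect_true(all(hl < 0.05))
  expect_true(all(abs(hl - hc) / hc < 0.10))
})

test_that("an interval with no at-risk rows raises an instructive error", {
  d <- data.frame(time = c(0.5, 0.7, 0.9), event = c(1, 1, 1), x1 = 1:3)
  expect_error(
    dtsurv(surv_formula, d, grid = interval_grid(c(0, 1, 5, 10))),
    "fewer intervals")
})

test_that("degenerate and custom classifiers obey the contract", {
  d <- data.frame(time = c(1.5, 2.5, 3.5, 4.5), event = c(1, 1, 1, 0),
                  x1 = rnorm(4))
  fit <- dtsurv(surv_formula, d, grid = unit_grid5(),
                engine = engine_constant(0.5))
  lam <- predict(fit, data.frame(x1 = 0), type = "hazard")
  expect_equal(as.numeric(lam), rep(0.5, 5))
  S <- predict(fit, data.frame(x1 = 0), times = c(1, 2))
  expect_equal(as.numeric(S), c(0.5, 0.25))

  bad <- dtsurv_engine("bad", fit = function(x, y, seed, params) NULL,
                       predict = function(state, x) rep(1.5, nrow(x)))
  fitb <- dtsurv(surv_formula, d, grid = unit_grid5(), engine = bad)
  expect_error(predict(fitb, data.frame(x1 = 0), type = "hazard"),
               "contract")
})

test_that("logistic engine matches the logit link model", {
  sim <- simulate_survival(400, family = "exponential", beta = c(0.5, -0.3),
                           n_covariates = 2, base_rate = 0.15,
                           censoring = "exponential", censor_rate = 0.25,
                           seed = 5)
  g <- quantile_grid(admin_censor(sim, 8), 8, 5)
  f1 <- dtsurv(survival::Surv(time, event) ~ x1 + x2, sim, grid = g,
               link = "logit")
  f2 <- dtsurv(survival::Surv(time, event) ~ x1 + x2, sim, grid = g,
               engine = engine_glm())
  nd <- data.frame(x1 = rnorm(10), x2 = rnorm(10))
  expect_equal(predict(f1, nd, type = "hazard"),
               predict(f2, nd, type = "hazard"), tolerance = 1e-4)
})

test_that("hazard predictions equal the classifier output on expanded rows", {
  sim <- simulate_survival(150, family = "exponential", beta = 0.6,
                           base_rate = 0.2, seed = 8)
  fit <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 4,
                engine = engine_rpart(), seed = 1)
  nd <- data.frame(x1 = c(-2, 0, 2))
  lam <- predict(fit, nd, type = "hazard")
  # direct recomputation through the engine on the expanded feature rows
  pe <- expand_prediction(nd, fit$grid, covariates = "x1")
  feats <- dtsurv:::engine_features(pe, fit)
  direct <- matrix(fit$engine$predict(fit$state, feats), nrow = 3,
                   byrow = TRUE)
  expect_equal(unname(lam), pmin(pmax(direct, 1e-6), 1 - 1e-6),
               tolerance = 1e-12)
  # permutation equivariance
  lam_rev <- predict(fit, nd[3:1, , drop = FALSE], type = "hazard")
  expect_equal(unname(lam_rev), unname(lam[3:1, ]))
})

test_that("survival composition is a valid monotone step function", {
  d <- data.frame(time = runif(60, 0.1, 4.9), event = rbinom(60, 1, 0.7),
                  x1 = rnorm(60))
  for (s in 1:5) {
    fit <- dtsurv(surv_formula, d, grid = unit_grid5(),
                  engine = engine_adversarial(s))
    tt <- sort(runif(20, 0, 5))
    S <- predict(fit, data.frame(x1 = rnorm(4)), times = tt)
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(apply(S, 1, function(z) all(diff(z) <= 1e-12))))
    # step behaviour: constant between consecutive cut points
    expect_equal(predict(fit, data.frame(x1 = 0), times = 2.1),
                 predict(fit, data.frame(x1 = 0), times = 2.9),
                 ignore_attr = TRUE)
  }
  # log-space composition agrees with the direct product
  fit <- dtsurv(surv_formula, d, grid = unit_grid5(), link = "logit")
  lam <- predict(fit, data.frame(x1 = 0.3), type = "hazard")
  S5 <- predict(fit, data.frame(x1 = 0.3), times = 5)
  expect_equal(as.numeric(S5), prod(1 - lam), tolerance = 1e-12)
  # zero hazards give survival one everywhere (up to clipping)
  f0 <- dtsurv(surv_formula, d, grid = unit_grid5(),
               engine = engine_constant(0))
  expect_equal(as.numeric(predict(f0, data.frame(x1 = 0), times = c(1, 5))),
               c(1, 1), tolerance = 1e-5)
  # extrapolation beyond the horizon is refused
  expect_error(predict(fit, data.frame(x1 = 0), times = 6), "horizon")
})

test_that("alternative links fit and produce valid hazards", {
  sim <- simulate_survival(500, family = "exponential", beta = 0.5,
                           base_rate = 0.15, seed = 21)
  nd <- data.frame(x1 = c(-1, 1))
  for (lk in c("probit", "loglog", "log")) {
    fit <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 4,
                  link = lk)
    lam <- predict(fit, nd, type = "hazard")
    expect_true(all(lam > 0 & lam < 1), info = lk)
    expect_true(all(diff(as.numeric(predict(fit, nd[1, , drop = FALSE],
                                            times = 1:4))) <= 0),
                info = lk)
  }
})

test_that("log-likelihood matches the subject-level product form", {
  # single subject, event in interval 1, constant hazard 0.3
  d1 <- data.frame(time = 0.5, event = 1, x1 = 0)
  f1 <- dtsurv(surv_formula, d1, grid = unit_grid5(),
               engine = engine_constant(0.3))
  expect_equal(hazard_loglik(f1), log(0.3), tolerance = 1e-12)

  # random data: row-level binomial sum vs per-subject product oracle
  sim <- simulate_survival(200, family = "exponential", beta = 0.5,
                           base_rate = 0.2, censoring = "exponential",
                           censor_rate = 0.3, seed = 12)
  fit <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 4,
                link = "logit")
  pp <- fit$pp
  lam <- dtsurv:::row_hazards(fit, pp)
  per_subject <- vapply(split(seq_len(nrow(pp)), pp$id), function(rows) {
    sum(log(lam[rows]^pp$d[rows] * (1 - lam[rows])^(1 - pp$d[rows])))
  }, numeric(1))
  expect_equal(hazard_loglik(fit), sum(per_subject), tolerance = 1e-12)

  # additivity: doubling every subject doubles the log-likelihood
  pp2 <- rbind(as.data.frame(pp), as.data.frame(pp))
  attr(pp2, "grid") <- fit$grid
  class(pp2) <- class(pp)
  expect_equal(hazard_loglik(fit, pp2), 2 * hazard_loglik(fit),
               tolerance = 1e-10)
})

test_that("engine fits are reproducible given a seed", {
  sim <- simulate_survival(250, family = "exponential", beta = 0.7,
                           base_rate = 0.2, seed = 31)
  nd <- data.frame(x1 = rnorm(5))
  f1 <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 4,
               engine = engine_ranger(num.trees = 50), seed = 99)
  f2 <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 4,
               engine = engine_ranger(num.trees = 50), seed = 99)
  expect_identical(predict(f1, nd, type = "hazard"),
                   predict(f2, nd, type = "hazard"))
})

test_that("a tree ensemble beats the linear logit model on a threshold effect", {
  sim <- simulate_survival(900, family = "exponential", beta = 0,
                           threshold = list(var = "x1", at = 0, effect = 2),
                           base_rate = 0.08, seed = 44)
  idx <- seq_len(600)
  train <- as.data.frame(sim)[idx, ]
  test <- as.data.frame(sim)[-idx, ]
  h <- 8
  times <- c(2, 4, 6, 8)
  fl <- dtsurv(surv_formula, train, horizon = h, n_intervals = 5,
               link = "logit")
  ft <- dtsurv(surv_formula, train, horizon = h, n_intervals = 5,
               engine = engine_ranger(num.trees = 200, min.node.size = 25),
               encoding = "ordinal", seed = 7)
  ibs_of <- function(fit) {
    risk <- predict(fit, test, type = "risk", times = times)
    evaluate_predictions(risk, times, test$time, test$event)$ibs
  }
  expect_lt(ibs_of(ft), ibs_of(fl))
})

test_that("model summaries expose coefficients and fit diagnostics", {
  sim <- simulate_survival(200, family = "exponential", beta = 0.5,
                           base_rate = 0.2, seed = 3)
  fit <- dtsurv(surv_formula, sim, horizon = 6, n_intervals = 3,
                link = "logit")
  s <- summary(fit)
  expect_s3_class(s, "summary.dtsurv")
  expect_true("x1" %in% rownames(s$coefficients))
  expect_output(print(s), "log-likelihood")
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 4L)
  expect_warning(coef(dtsurv(surv_formula, sim, horizon = 6,
                             n_intervals = 3,
                             engine = engine_constant(0.2))),
                 "link-based")
  # simulate() round-trip returns plausible discrete data
  rep1 <- simulate(fit, nsim = 1, seed = 5)[[1]]
  expect_true(all(rep1$time %in% fit$grid$cut_points[-1]))
})
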