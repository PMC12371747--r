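test_that("the binomial log-likelihood matches term-by-term summation", {
  expect_equal(log_likelihood(c(0.5, 0.5), c(0, 1)), 2 * log(0.5))
  # near-perfect predictions approach zero from below
  eps <- 1e-12
  expect_lt(abs(log_likelihood(c(eps, 1 - eps), c(0, 1))), 1e-11)
  expect_error(log_likelihood(c(0, 0.5), c(1, 0)), "-Inf")

  set.seed(41)
  p <- runif(300, 0.01, 0.99)
  y <- rbinom(300, 1, p)
  oracle <- sum(vapply(seq_along(p), function(i) {
    if (y[i] == 1) log(p[i]) else log(1 - p[i])
  }, numeric(1)))
  expect_equal(log_likelihood(p, y), oracle, tolerance = 1e-12)
})

test_that("calibration-in-the-large returns means and the offset intercept", {
  # predictions identically at the prevalence: intercept exactly 0
  y <- rep(c(1, 0), c(3, 7))
  p <- rep(0.3, 10)
  ci <- calibration_in_the_large(p, y)
  expect_equal(ci$mean_predicted, 0.3)
  expect_equal(ci$observed_rate, 0.3)
  expect_equal(ci$intercept, 0, tolerance = 1e-8)

  # consistency: outcomes drawn from p give intercept near 0
  set.seed(42)
  p2 <- runif(2e4, 0.05, 0.95)
  y2 <- rbinom(2e4, 1, p2)
  expect_lt(abs(calibration_in_the_large(p2, y2)$intercept), 0.05)

  # a +0.5 logit overprediction is recovered as intercept ~ -0.5
  p3 <- plogis(qlogis(p2) + 0.5)
  y3 <- rbinom(2e4, 1, p2)
  expect_lt(abs(calibration_in_the_large(p3, y3)$intercept + 0.5), 0.06)

  expect_warning(res <- calibration_in_the_large(c(0.2, 0.3), c(0, 0)),
                 "constant")
  expect_true(is.na(res$intercept))
  expect_equal(res$observed_rate, 0)
})

test_that("calibration slope and intercept are the joint logistic MLE", {
  set.seed(43)
  n <- 1e5
  lp <- rnorm(n, -0.5, 1.2)
  y <- rbinom(n, 1, plogis(lp))
  ab <- calibration_slope_intercept(lp, y)
  expect_true(ab["slope"] > 0.95 && ab["slope"] < 1.05)
  expect_true(abs(ab["intercept"]) < 0.05)

  # outcomes unrelated to lp: slope near 0
  y_ind <- rbinom(n, 1, 0.3)
  ab0 <- calibration_slope_intercept(lp, y_ind)
  expect_lt(abs(ab0["slope"]), 0.05)

  expect_error(calibration_slope_intercept(lp[1:5], rep(1, 5)),
               "both outcome classes")
})

test_that("equal-count calibration bins have the documented sizes", {
  set.seed(44)
  p <- runif(674, 0.05, 0.9)
  y <- rbinom(674, 1, p)
  curve <- calibration_curve(p, y, n_bins = 10)
  expect_equal(sort(unique(curve$n)), c(67, 68))
  expect_equal(sum(curve$n), 674)
  expect_equal(sum(curve$n == 68), 4)  # remainder spread over lowest bins

  # constant predictions collapse to one effective bin
  expect_warning(flat <- calibration_curve(rep(0.3, 10),
                                           rep(c(1, 0), c(3, 7)), 10),
                 "merged")
  expect_equal(nrow(flat), 1)
  expect_equal(flat$observed, 0.3)
  expect_equal(flat$mean_predicted, 0.3)
})

test_that("calibration bins match an independent sort-and-slice oracle", {
  set.seed(45)
  n <- 237
  p <- runif(n)
  y <- rbinom(n, 1, p)
  g <- 10
  curve <- calibration_curve(p, y, n_bins = g)
  ord <- order(p)
  sizes <- rep(n %/% g, g)
  sizes[seq_len(n %% g)] <- sizes[seq_len(n %% g)] + 1
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  oracle <- data.frame(
    bin = 1:g,
    n = sizes,
    mean_predicted = mapply(function(a, b) mean(p[ord][a:b]), starts, stops),
    observed = mapply(function(a, b) mean(y[ord][a:b]), starts, stops))
  expect_equal(curve, oracle, tolerance = 1e-12)
})

test_that("the Hosmer-Lemeshow statistic matches hand arithmetic", {
  # two risk groups of 50, mean predictions 0.2 / 0.4, observed 15 / 25
  p <- rep(c(0.2, 0.4), each = 50)
  y <- c(rep(c(1, 0), c(15, 35)), rep(c(1, 0), c(25, 25)))
  hl <- hosmer_lemeshow(p, y, g = 2, df = "g")
  hand <- (15 - 10)^2 / (50 * 0.2 * 0.8) + (25 - 20)^2 / (50 * 0.4 * 0.6)
  expect_equal(hl$statistic, hand, tolerance = 1e-10)
  expect_equal(hl$df, 2)
  expect_equal(hl$p_value, pchisq(hand, 2, lower.tail = FALSE))

  # O = E in every bin: statistic 0, p = 1
  p0 <- rep(c(0.2, 0.4), each = 50)
  y0 <- c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(20, 30)))
  hl0 <- hosmer_lemeshow(p0, y0, g = 2, df = "g")
  expect_equal(hl0$statistic, 0)
  expect_equal(hl0$p_value, 1)

  # df conventions
  set.seed(46)
  p1 <- runif(200, 0.05, 0.95)
  y1 <- rbinom(200, 1, p1)
  expect_equal(hosmer_lemeshow(p1, y1, 10, df = "g-2")$df, 8)
  expect_equal(hosmer_lemeshow(p1, y1, 10, df = "g")$df, 10)
  expect_gte(hosmer_lemeshow(p1, y1, 10)$statistic, 0)
})

test_that("the Brier score is the mean squared prediction error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  set.seed(47)
  p <- runif(100)
  y <- rbinom(100, 1, p)
  expect_equal(brier(p, y), mean((p - y)^2))
  # constant-prevalence predictor scores exactly prev * (1 - prev)
  prev <- mean(y)
  expect_equal(brier(rep(prev, 100), y), prev * (1 - prev))
})

test_that("AUC is the tie-corrected rank-sum concordance probability", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "single outcome class")

  set.seed(48)
  p <- round(runif(150), 2)  # force some ties
  y <- rbinom(150, 1, p)
  # exhaustive pair-counting oracle with half-credit for ties
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc(p, y), mean(cmp), tolerance = 1e-12)

  # invariance under strictly increasing transforms
  expect_equal(auc(plogis(5 * qlogis(pmin(pmax(p, 0.01), 0.99))), y),
               auc(pmin(pmax(p, 0.01), 0.99), y))

  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                             direction = "<")))
  expect_equal(auc(p, y), proc_auc, tolerance = 1e-12)
})

test_that("validate_model assembles the full metric bundle coherently", {
  set.seed(49)
  f <- random_features(400)
  m <- lipp_model()
  m$intercept <- -7
  y <- rbinom(400, 1, predict(m, f))
  rep <- validate_model(m, f, y)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$n, 400)
  expect_equal(rep$observed_rate, rep$n_events / rep$n)
  expect_equal(rep$mean_predicted, mean(predict(m, f)))
  expect_equal(sum(rep$calibration_curve$n), 400)
  expect_true(rep$brier >= 0 && rep$brier <= 1)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_equal(rep$log_likelihood, log_likelihood(predict(m, f), y))
})
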