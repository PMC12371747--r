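feat <- function(parotid, smg, baseline = "none") {
  data.frame(parotid_sum = parotid, smg = smg, baseline = baseline)
}

test_that("the published baseline scores are tabulated exactly", {
  m <- lipp_model()
  expect_equal(baseline_score(m, "none"), 0)
  expect_equal(baseline_score(m, "mild"), 0.459)
  expect_equal(baseline_score(m, "moderate_severe"), 1.207)
  expect_error(baseline_score(m, "severe"), "unknown baseline")
})

test_that("the linear predictor matches the published formula", {
  m <- lipp_model()
  expect_equal(linear_predictor(m, feat(0, 0)), -2.2951)
  expect_equal(linear_predictor(m, feat(0, 0, "mild")), -2.2951 + 0.459)
  expect_equal(linear_predictor(m, feat(10, 10)),
               -2.2951 + 0.996 + 0.182, tolerance = 1e-12)
  expect_error(linear_predictor(m, feat(-1, 10)), ">= 0")
})

test_that("predicted probabilities are the inverse logit of S", {
  m0 <- ntcp_model(0, 0.1, 0.02)
  expect_equal(predict(m0, feat(0, 0)), 0.5)

  m <- lipp_model()
  expect_equal(predict(m, feat(0, 0)), 1 / (1 + exp(2.2951)))
  expect_equal(round(predict(m, feat(0, 0)), 4), 0.0915)

  # monotone in each dose feature with positive coefficients
  expect_gt(predict(m, feat(50, 40)), predict(m, feat(40, 40)))
  expect_gt(predict(m, feat(40, 50)), predict(m, feat(40, 40)))

  # predict is exactly plogis of the linear predictor
  set.seed(31)
  f <- random_features(200)
  expect_equal(predict(m, f), plogis(linear_predictor(m, f)),
               tolerance = 1e-12)
})

test_that("the sqrt dose transform is applied per dose term", {
  m <- lipp_model(dose_transform = "sqrt")
  expect_equal(linear_predictor(m, feat(49, 64)),
               -2.2951 + 0.0996 * 7 + 0.0182 * 8, tolerance = 1e-12)
})

test_that("recalibration preserves the dose-coefficient ratio exactly", {
  set.seed(32)
  f <- random_features(800)
  m <- lipp_model()
  lp <- linear_predictor(m, f)
  y <- rbinom(800, 1, plogis(0.3 + 0.7 * lp))
  up <- update_model(m, y, level = "recalibration", features = f)
  expect_equal(up$coef_parotid / up$coef_smg, 0.0996 / 0.0182,
               tolerance = 1e-12)
})

test_that("recalibration folds (a, b) into exactly equivalent coefficients", {
  set.seed(33)
  f <- random_features(600)
  m <- lipp_model()
  lp <- linear_predictor(m, f)
  y <- rbinom(600, 1, plogis(-1 + 1.3 * lp))
  up <- update_model(m, y, level = "recalibration", features = f)
  lp_up <- linear_predictor(up, f)
  # affine in the original lp: residuals of a linear fit vanish
  co <- coef(lm(lp_up ~ lp))
  expect_equal(unname(lp_up), unname(co[1] + co[2] * lp), tolerance = 1e-10)
  # self-consistency on the fitting data
  ab <- calibration_slope_intercept(lp_up, y)
  expect_equal(unname(ab["slope"]), 1, tolerance = 1e-6)
  expect_equal(unname(ab["intercept"]), 0, tolerance = 1e-6)
})

test_that("recalibration recovers a unit slope on model-generated data", {
  set.seed(34)
  n <- 1e5
  f <- random_features(n)
  m <- lipp_model()
  # use a model whose predictions are not saturated at these doses
  m$intercept <- -7
  lp <- linear_predictor(m, f)
  y <- rbinom(n, 1, plogis(lp))
  up <- update_model(m, y, level = "recalibration", features = f, lp = lp)
  b <- up$coef_parotid / m$coef_parotid
  expect_lt(abs(b - 1), 0.05)
})

test_that("the intercept update solves the offset score equation", {
  set.seed(35)
  n <- 5e4
  f <- random_features(n)
  m <- lipp_model()
  m$intercept <- -7
  lp <- linear_predictor(m, f)
  y <- rbinom(n, 1, plogis(lp))
  up <- update_model(m, y, level = "intercept", features = f, lp = lp)
  expect_lt(abs(up$intercept - m$intercept), 0.05)
  expect_equal(up$coef_parotid, m$coef_parotid)  # only the intercept moves
  # a pure intercept shift in the truth is recovered
  y2 <- rbinom(n, 1, plogis(lp - 0.6))
  up2 <- update_model(m, y2, level = "intercept", features = f, lp = lp)
  expect_lt(abs((up2$intercept - m$intercept) + 0.6), 0.06)
})

test_that("revision refits intercept and dose coefficients by ML", {
  set.seed(36)
  n <- 4e4
  f <- random_features(n)
  truth <- ntcp_model(-4, 0.07, 0.03)
  y <- rbinom(n, 1, predict(truth, f))
  rev <- update_model(lipp_model(), y, level = "revision", features = f)
  expect_lt(abs(rev$intercept - truth$intercept), 0.25)
  expect_lt(abs(rev$coef_parotid - truth$coef_parotid), 0.01)
  expect_lt(abs(rev$coef_smg - truth$coef_smg), 0.01)
})

test_that("every update level improves the in-sample log-likelihood", {
  set.seed(37)
  f <- random_features(500)
  m <- lipp_model()
  y <- rbinom(500, 1, plogis(-0.8 + 1.2 * linear_predictor(m, f)))
  ll0 <- log_likelihood(predict(m, f), y)
  for (lev in c("intercept", "recalibration", "revision")) {
    up <- update_model(m, y, level = lev, features = f)
    expect_gte(log_likelihood(predict(up, f), y), ll0 - 1e-10)
  }
})

test_that("update fitting errors are classed and informative", {
  f <- feat(c(10, 20, 30), c(10, 20, 30))
  expect_error(update_model(lipp_model(), c(1, 1, 1), "recalibration",
                            features = f), "constant")
  expect_error(update_model(lipp_model(), c(0, 1, 0), "revision"),
               "features")
})

test_that("models serialize to JSON and back without loss", {
  m <- lipp_recalibrated_model()
  f <- tempfile(fileext = ".json")
  write_ntcp_model(m, f)
  back <- read_ntcp_model(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coef_parotid, m$coef_parotid)
  expect_equal(back$baseline_scores, m$baseline_scores)
  expect_equal(back$dose_transform, m$dose_transform)
  unlink(f)

  shipped <- read_ntcp_model(system.file("extdata", "lipp_model.json",
                                         package = "ntcpval"))
  expect_equal(shipped$intercept, -2.2951)
  expect_equal(shipped$coef_parotid, 0.0996)
  expect_equal(shipped$coef_smg, 0.0182)
  recal <- read_ntcp_model(system.file("extdata",
                                       "lipp_recalibrated_model.json",
                                       package = "ntcpval"))
  expect_equal(recal$intercept, -3.2132)
  expect_equal(recal$coef_parotid, 0.1354)
  expect_equal(recal$coef_smg, 0.0247)
})
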