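test_that("deviance inversion round-trips binary observations exactly", {
  p <- c(0.05, 0.2, 0.5, 0.7, 0.95)
  d1 <- sign(1 - p) * sqrt(-2 * log(p))          # y = 1 residuals
  d0 <- -sqrt(-2 * log(1 - p))                   # y = 0 residuals
  expect_equal(invert_deviance(d1, p), 1 - p, tolerance = 1e-9)
  expect_equal(invert_deviance(d0, p), -p, tolerance = 1e-9)
  expect_equal(invert_deviance(0, 0.37), 0)
  expect_error(invert_deviance(1, 1), "\\(0, 1\\)")
})

test_that("deviance inversion agrees with a bisection oracle and clamps", {
  # worked value: p = 0.5, d = sqrt(2 log 2) = 1.17741 -> u = 1, r = 0.5
  expect_equal(invert_deviance(1.17741, 0.5), 0.5, tolerance = 1e-4)

  # independent oracle: bisect the continuous deviance directly
  dev_fun <- function(u, p) {
    t1 <- if (u == 0) 0 else u * log(u / p)
    t2 <- if (u == 1) 0 else (1 - u) * log((1 - u) / (1 - p))
    sign(u - p) * sqrt(2 * (t1 + t2))
  }
  for (p in c(0.3, 0.6)) for (d in c(-0.8, -0.2, 0.4, 1.0)) {
    lo <- 0; hi <- 1
    for (k in 1:80) {
      mid <- (lo + hi) / 2
      if (dev_fun(mid, p) < d) lo <- mid else hi <- mid
    }
    expect_equal(invert_deviance(d, p), (lo + hi) / 2 - p, tolerance = 1e-6,
                 info = sprintf("p=%g d=%g", p, d))
  }

  # values beyond the attainable interval clamp to the boundary residual
  expect_equal(invert_deviance(50, 0.25), 0.75, tolerance = 1e-9)
  expect_equal(invert_deviance(-50, 0.25), -0.25, tolerance = 1e-9)

  # identity mode passes the kriged value through
  expect_equal(invert_deviance(0.3, 0.5, mode = "identity"), 0.3)
})

test_that("prediction assembly sums trend and residual with clipping", {
  trend <- data.frame(id = c("a", "b", "c"), p = c(0.4, 0.9, 0.5))
  kriged <- data.frame(id = c("a", "b", "c"),
                       predicted_residual = c(0, 2.5, 0))
  obs <- data.frame(id = c("a", "b", "c"), y = c(0, 1, 1))
  rec <- assemble_predictions(trend, kriged, obs, mode = "identity")
  expect_equal(rec$y_hat, c(0.4, 1.0, 0.5))   # zero residual passes p through; clip at 1
  expect_equal(rec$raw_residual[1], 0)
  expect_error(assemble_predictions(trend, kriged[1:2, ], obs), "orphan")

  # additive mid-range case
  rec2 <- assemble_predictions(data.frame(id = "a", p = 0.4),
                               data.frame(id = "a", predicted_residual = 0.25),
                               data.frame(id = "a", y = 1), mode = "identity")
  expect_equal(rec2$y_hat, 0.65)
})

test_that("RMSPE matches closed forms", {
  expect_equal(rmspe(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(rmspe(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(rmspe(numeric(), numeric()), "no records")
  # clipping to [0, 1] never hurts RMSPE against binary outcomes
  y <- withr::with_seed(1, stats::rbinom(200, 1, 0.5))
  raw <- withr::with_seed(2, stats::rnorm(200, y, 0.8))
  expect_lte(rmspe(y, pmin(pmax(raw, 0), 1)), rmspe(y, raw))
})

test_that("ROC AUC equals exhaustive pair enumeration with half ties", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.3, 0.5, 0.5)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  bf <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                    ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(roc_auc(y, s), bf)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_warning(a <- roc_auc(c(1, 1), c(0.2, 0.4)), "single-class")
  expect_true(is.na(a))

  # larger random case against brute force and pROC, plus monotone invariance
  yy <- withr::with_seed(4, stats::rbinom(150, 1, 0.4))
  ss <- withr::with_seed(5, round(stats::rnorm(150, yy), 1))  # with ties
  pr <- expand.grid(i = which(yy == 1), j = which(yy == 0))
  bf2 <- mean(ifelse(ss[pr$i] > ss[pr$j], 1,
                     ifelse(ss[pr$i] == ss[pr$j], 0.5, 0)))
  expect_equal(roc_auc(yy, ss), bf2, tolerance = 1e-12)
  expect_equal(roc_auc(yy, stats::plogis(3 * ss + 1)), bf2, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(roc_auc(yy, ss),
                 as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("percent changes reproduce the published arithmetic", {
  expect_equal(round(percent_change(0.755, 0.856), 1), 13.4)
  expect_equal(round(percent_change(0.856, 0.919), 2), 7.36)
  expect_equal(round(percent_change(0.3940, 0.3376), 2), -14.31)
  expect_equal(percent_change(2, 2), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("accuracy labels follow the half-open AUC taxonomy", {
  expect_equal(accuracy_label(c(0.583, 0.95, 0.5)),
               c("less than Acceptable", "Outstanding", "None"))
  expect_equal(accuracy_label(c(0.7, 0.8, 0.9)),
               c("Acceptable", "Excellent", "Outstanding"))
  expect_equal(accuracy_label(0.7999), "Acceptable")
  expect_error(accuracy_label(1.2), "\\[0, 1\\]")
})

test_that("results-table summaries count a toy table correctly", {
  t2 <- data.frame(item = "i1", detrending = c("spatial", "spatial_rater"),
                   nugget = c(0.5, 0.4), rmspe = c(0.3, 0.29),
                   rmspe_pct_change = c(NA, -3.3))
  t3 <- data.frame(item = "i1", group = "disorder",
                   detrending = c("spatial", "spatial_rater"),
                   auc_large = c(0.7, 0.72), auc_full = c(0.91, 0.95),
                   auc_pct_change_rater = c(NA, 4.4))
  s <- summarize_results_table(t2, t3)
  expect_equal(s$full_outstanding, 2L)
  expect_equal(s$full_below_acceptable, 0L)
  expect_equal(s$items_rater_auc_improved, 1L)
  expect_equal(s$items_rater_rmspe_lower, 1L)
  expect_equal(s$items_rater_nugget_lower, 1L)
  expect_equal(s$full_beats_large, 2L)
  expect_error(summarize_results_table(t2[1, ], t3), "incomplete")
})
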