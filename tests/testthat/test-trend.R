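test_that("design matrix centers coordinates and expands the cubic terms", {
  pts <- make_points(200, seed = 3)
  pts$rater <- factor(rep(c("r1", "r2", "r3", "r4"), 50))
  des <- build_design(pts, trend_spec())
  expect_lt(abs(mean(des$X[, "x"])), 1e-9)
  expect_lt(abs(mean(des$X[, "y"])), 1e-9)
  expect_equal(ncol(des$X), 8L)  # intercept + 7 spatial terms
  expect_equal(colnames(des$X),
               c("(Intercept)", "x", "y", "x2", "y2", "xy", "x3", "y3"))

  des9 <- build_design(pts, trend_spec(terms = "cubic9"))
  expect_equal(ncol(des9$X), 10L)

  desr <- build_design(pts, trend_spec(include_rater = TRUE))
  expect_equal(ncol(desr$X), 11L)  # + 3 rater dummies
  expect_equal(desr$rater_levels[1L], "r4")  # last level is the reference
  ref_rows <- pts$rater == "r4"
  expect_true(all(desr$X[ref_rows, c("raterr1", "raterr2", "raterr3")] == 0))

  expect_error(trend_spec(terms = list(c(2, 2))), "degree")
  expect_warning(build_design(data.frame(x = c(0, 0), y = c(0, 1)),
                              trend_spec()), "constant")
})

test_that("logistic trend fits match glm and recover simulated effects", {
  # flat surface + rater offsets; no latent field
  spec <- simulation_spec(
    trend_coefficients = rep(0, 8),
    rater_effects = c(0.5, 0, -0.5, 0),
    latent_model = nested_variogram(0, vgm_structure("nugget", 0)),
    seed = 11)
  pts <- make_points(2000, seed = 11)
  ds <- simulate_responses(pts, rep(0, 2000), spec)
  m <- fit_trend(ds, "item_synthetic", trend_spec(include_rater = TRUE))

  # independent oracle: the same model through the stats::glm formula API
  cx <- (ds$x - mean(ds$x)) / 1000; cy <- (ds$y - mean(ds$y)) / 1000
  r <- stats::relevel(factor(ds$rater), ref = "r4")
  y <- recode_response(ds$item_synthetic)
  g <- stats::glm(y ~ cx + cy + I(cx^2) + I(cy^2) + I(cx * cy) +
                    I(cx^3) + I(cy^3) + r, family = stats::binomial())
  expect_equal(unname(m$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(max(abs(score_trend(m, ds) - fitted(g))), 0, tolerance = 1e-10)

  # spatial coefficients generated as zero: recovered within 3 SE of 0;
  # rater contrasts vs reference recovered within 3 SE of (0.5, 0, -0.5)
  se <- summary(g)$coefficients[, "Std. Error"]
  est <- coef(g)
  expect_true(all(abs(est[2:8]) < 3 * se[2:8]))
  truth <- c(0.5, 0, -0.5)   # r1, r2, r3 relative to r4's 0
  expect_true(all(abs(est[9:11] - truth) < 3 * se[9:11]))
})

test_that("intercept-only data at prevalence one half fits a near-zero intercept", {
  spec <- simulation_spec(trend_coefficients = rep(0, 8),
                          rater_effects = rep(0, 4),
                          latent_model = nested_variogram(0, vgm_structure("nugget", 0)),
                          seed = 21)
  ds <- make_sim_dataset(n = 2000, seed = 21, spec = spec)
  m <- fit_trend(ds, "item_synthetic")
  expect_lt(abs(m$coefficients[["(Intercept)"]]), 0.15)
  expect_equal(unname(score_trend(
    structure(list(item = "i", coefficients = rep(0, 8), spec = trend_spec(),
                   center = c(0, 0), rater_levels = NULL),
              class = "trend_model"),
    data.frame(x = c(10, -400), y = c(5, 800)))), c(0.5, 0.5))
})

test_that("scoring equals the inverse logit of the design dot product", {
  m <- fit_trend(make_sim_dataset(n = 300, seed = 7), "item_synthetic")
  loc <- data.frame(x = c(100, 900, 2500, 4000, 6000),
                    y = c(50, 2200, 700, 5100, 3000))
  # brute-force linear algebra with explicit powers
  cx <- (loc$x - m$center[1]) / 1000; cy <- (loc$y - m$center[2]) / 1000
  X <- cbind(1, cx, cy, cx^2, cy^2, cx * cy, cx^3, cy^3)
  expect_equal(score_trend(m, loc),
               1 / (1 + exp(-drop(X %*% m$coefficients))), tolerance = 1e-12)
})

test_that("unseen rater levels error unless the reference fallback is chosen", {
  ds <- make_sim_dataset(n = 400, seed = 9)
  m <- fit_trend(ds, "item_synthetic", trend_spec(include_rater = TRUE))
  loc <- data.frame(x = 100, y = 100, rater = "r9")
  expect_error(score_trend(m, loc), "unseen rater")
  p_ref <- score_trend(m, transform(loc, rater = m$rater_levels[1L]))
  expect_equal(score_trend(m, loc, fallback_reference = TRUE), p_ref)
})

test_that("deviance residuals follow the closed form and sum to the model deviance", {
  # closed-form values at p = 1/2
  ds <- make_sim_dataset(n = 600, seed = 13)
  m <- fit_trend(ds, "item_synthetic")
  res <- deviance_residuals(m, ds)
  y <- recode_response(ds$item_synthetic)
  p <- score_trend(m, ds)
  expect_equal(sign(res$residual), sign(y - p))
  expect_equal(sum(res$residual^2), m$deviance, tolerance = 1e-6)

  # hand values: y = 1 / 0 at p = 0.5
  hand <- structure(list(item = "i", coefficients = rep(0, 8),
                         spec = trend_spec(), center = c(0, 0),
                         rater_levels = NULL), class = "trend_model")
  toy <- audit_dataset(data.frame(id = c("a", "b"), x = c(0, 1), y = c(0, 1),
                                  rater = "r1", item_i = c(1, 2)))
  hand$item <- "item_i"
  r <- deviance_residuals(hand, toy)
  expect_equal(r$residual, c(1, -1) * sqrt(2 * log(2)), tolerance = 1e-9)
})

test_that("adding rater dummies never increases training deviance", {
  ds <- make_sim_dataset(n = 800, seed = 17,
                         spec = simulation_spec(rater_effects = c(1, 0, -1, 0),
                                                seed = 17))
  m0 <- fit_trend(ds, "item_synthetic", trend_spec())
  m1 <- fit_trend(ds, "item_synthetic", trend_spec(include_rater = TRUE))
  expect_lte(m1$deviance, m0$deviance + 1e-8)
})

test_that("trend models survive a JSON round trip", {
  ds <- make_sim_dataset(n = 300, seed = 19)
  m <- fit_trend(ds, "item_synthetic", trend_spec(include_rater = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  trend_to_json(m, path)
  back <- trend_from_json(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$center, unname(m$center), ignore_attr = TRUE)
  expect_equal(score_trend(back, ds, rater = as.character(ds$rater)),
               score_trend(m, ds), tolerance = 1e-12)
})

test_that("single-class items refuse to fit", {
  df <- data.frame(id = as.character(1:30), x = runif(30), y = runif(30),
                   rater = "r1", item_k = rep(1, 30))
  expect_error(fit_trend(audit_dataset(df), "item_k"), "single response class")
})
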