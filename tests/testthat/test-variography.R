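test_that("the Matheron estimator reproduces hand-computed values", {
  # two points, values 0 and 2, one bin: gamma = (1/2) * (2)^2 / 1 = 2
  emp <- empirical_semivariogram(
    data.frame(x = c(0, 1000), y = c(0, 0), residual = c(0, 2)),
    max_lag = 2, n_lags = 1)
  expect_equal(emp$gamma, 2)
  expect_equal(emp$np, 1)

  # constant field: zero in every non-empty bin
  fld <- make_points(80, seed = 2)
  fld$residual <- 5
  empc <- empirical_semivariogram(fld, n_lags = 10)
  expect_true(all(empc$gamma[empc$np > 0] == 0))

  # brute-force oracle on a small field
  fld$residual <- withr::with_seed(3, stats::rnorm(80))
  emp2 <- empirical_semivariogram(fld, max_lag = 4, n_lags = 8)
  d <- as.matrix(stats::dist(cbind(fld$x, fld$y) / 1000))
  v <- outer(fld$residual, fld$residual, "-")^2
  ut <- upper.tri(d)
  for (k in seq_len(8)) {
    sel <- ut & d > (k - 1) * 0.5 & d <= k * 0.5
    if (!any(sel)) next
    expect_equal(emp2$gamma[k], sum(v[sel]) / (2 * sum(sel)), tolerance = 1e-12)
    expect_equal(emp2$np[k], sum(sel))
  }

  # estimator symmetry under point-order reversal
  emp3 <- empirical_semivariogram(fld[rev(seq_len(80)), ], max_lag = 4,
                                  n_lags = 8)
  expect_equal(emp3$gamma, emp2$gamma)
})

test_that("an iid field has a flat semivariogram at its variance", {
  fld <- make_points(900, seed = 5)
  fld$residual <- withr::with_seed(6, stats::rnorm(900))
  emp <- empirical_semivariogram(fld, n_lags = 12)
  ok <- emp$np > 30
  # squared pair differences / 2 are scaled chi-square(1): var = 2 gamma^2
  se <- sqrt(2 / emp$np[ok])
  expect_true(all(abs(emp$gamma[ok] - 1) < 4 * se + 0.05))
})

test_that("theoretical families evaluate to their defining values", {
  sph <- nested_variogram(0.2, vgm_structure("spherical", 1, 2))
  expect_equal(model_semivariance(sph, 2), 1.2)      # nugget + sill at range
  expect_equal(model_semivariance(sph, 0), 0)        # gamma(0) = 0
  expect_equal(model_semivariance(sph, 1e-12), 0.2, tolerance = 1e-6)
  expect_error(model_semivariance(sph, -1), "negative")

  # published worked example: nested sill is the sum of components
  garbage <- nested_variogram(0.935, list(
    vgm_structure("matern", 0.13, 0.871),
    vgm_structure("sine_hole", 0.063, 4.731)))
  expect_equal(total_sill(garbage), 1.128)

  # power model has no finite sill; exponent restricted to (0, 2]
  pw <- nested_variogram(0.1, vgm_structure("power", 0.5, 1.5))
  expect_true(is.na(total_sill(pw)))
  expect_equal(model_semivariance(pw, 2), 0.1 + 0.5 * 2^1.5)
  expect_error(vgm_structure("power", 1, 2.5), "power exponent")

  # sine hole oscillates: gamma exceeds the sill near the first peak
  sh <- nested_variogram(0, vgm_structure("sine_hole", 1, 1))
  expect_gt(model_semivariance(sh, 1.5), 1)

  # monotone families are non-decreasing on a dense grid
  h <- seq(0, 10, length.out = 400)
  for (fam in c("spherical", "exponential", "gaussian", "cubic")) {
    g <- model_semivariance(nested_variogram(0.1, vgm_structure(fam, 1, 2)), h)
    expect_true(all(diff(g) > -1e-12), info = fam)
  }
  g <- model_semivariance(nested_variogram(0, vgm_structure("power", 0.5, 1)), h)
  expect_true(all(diff(g) > -1e-12))
})

test_that("weighted least squares recovers exact curves and prefers true nesting", {
  true <- nested_variogram(0.2, vgm_structure("spherical", 1, 2))
  fit <- fit_nested_wls(make_emp(true), families = "spherical",
                        max_structures = 1L)
  expect_equal(fit$nugget, 0.2, tolerance = 1e-3)
  expect_equal(fit$structures[[1L]]$psill, 1, tolerance = 1e-3)
  expect_equal(fit$structures[[1L]]$range, 2, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-8)

  # reported SSE must equal an independent recomputation from the bins
  emp <- make_emp(true)
  g_mod <- model_semivariance(fit, emp$lag)
  sse <- sum(emp$np * (emp$gamma - g_mod)^2 / g_mod^2)
  expect_equal(fit$sse, sse, tolerance = 1e-9)

  # nested truth: the nested candidate beats every single-family candidate
  true2 <- nested_variogram(0.1, list(
    vgm_structure("exponential", 0.5, 0.3),
    vgm_structure("spherical", 0.5, 3)))
  fit2 <- fit_nested_wls(make_emp(true2),
                         families = c("exponential", "spherical"),
                         max_structures = 2L)
  led <- attr(fit2, "candidates")
  expect_equal(length(fit2$structures), 2L)
  singles <- led[led$n_par == 3L, ]
  expect_true(all(fit2$sse < singles$sse))
  expect_error(fit_nested_wls(make_emp(true, n_lags = 3)), "at least 5")
})

test_that("anisotropy classification distinguishes isotropic and stretched fields", {
  # identical directional models are exactly isotropic
  mm <- nested_variogram(0.1, vgm_structure("spherical", 1, 1))
  dm <- stats::setNames(rep(list(mm), 8), sprintf("%g", seq(0, 157.5, 22.5)))
  expect_equal(classify_anisotropy(dm, mm, 4), "None")

  fit1 <- function(e) fit_nested_wls(e, families = "spherical",
                                     max_structures = 1L)
  classify_from <- function(fld) {
    emp <- empirical_semivariogram(fld, n_lags = 20)
    omni <- fit1(emp)
    de <- directional_semivariograms(fld, max_lag = attr(emp, "max_lag"),
                                     n_lags = 20)
    df <- lapply(de, function(e) tryCatch(fit1(e), error = function(err) NULL))
    classify_anisotropy(df, omni, attr(emp, "max_lag"))
  }
  pts <- make_points(2000, extent = c(0, 8000, 0, 8000), seed = 4)
  m <- nested_variogram(0.02, vgm_structure("spherical", 1, 0.8))

  f_iso <- simulate_latent_field(pts, m, seed = 101)
  expect_equal(classify_from(data.frame(x = pts$x, y = pts$y,
                                        residual = f_iso)), "None")

  # 3:1 geometric anisotropy with the long axis along x
  stretched <- data.frame(x = pts$x / 3, y = pts$y)
  f_an <- simulate_latent_field(stretched, m, seed = 201)
  lab <- classify_from(data.frame(x = pts$x, y = pts$y, residual = f_an))
  expect_match(lab, "^Yes")
  expect_equal(lab, "Yes, 0")
})
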