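#' Region specification for synthetic audit-location generation
#'
#' Defaults emulate a county-sized, densely sampled audit region: a
#' 22 x 15 km rectangle (330 km^2), target point spacing 150 m with a
#' 18 m tolerance band on the achieved mean nearest-neighbor distance, and
#' a point budget of about 25.3 points per km^2.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in meters.
#' @param target_spacing target mean nearest-neighbor distance, meters.
#' @param spacing_sd tolerance band (one SD) around the target, meters.
#' @param n_target number of points; default scales the extent area at
#'   25.3 points per km^2.
#' @param seed integer seed.
#' @return a `region_spec`.
#' @export
region_spec <- function(extent = c(0, 22000, 0, 15000), target_spacing = 150,
                        spacing_sd = 18, n_target = NULL, seed = 1L) {
  area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  if (area <= 0) stop("extent area must be > 0")
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  n_target <- n_target %||% round(area / 1e6 * 25.3)
  structure(list(extent = extent, target_spacing = target_spacing,
                 spacing_sd = spacing_sd, n_target = as.integer(n_target),
                 seed = as.integer(seed)),
            class = "region_spec")
}

## Sequential hard-core sampler: uniform proposals, accepted when no
## previously accepted point lies within `separation`. Cell-grid accelerated.
sample_hardcore <- function(n, extent, separation, max_proposals = 80L * n) {
  xs <- numeric(n); ys <- numeric(n)
  cell <- max(separation, 1e-9)
  ncx <- max(1L, ceiling((extent[2] - extent[1]) / cell))
  grid <- new.env(hash = TRUE, size = 4L * n)
  accepted <- 0L
  proposals <- 0L
  while (accepted < n && proposals < max_proposals) {
    m <- min(4096L, max_proposals - proposals)
    px <- stats::runif(m, extent[1], extent[2])
    py <- stats::runif(m, extent[3], extent[4])
    proposals <- proposals + m
    for (t in seq_len(m)) {
      cx <- floor((px[t] - extent[1]) / cell)
      cy <- floor((py[t] - extent[3]) / cell)
      ok <- TRUE
      for (dx in -1:1) {
        for (dy in -1:1) {
          key <- as.character((cx + dx) + (cy + dy) * ncx)
          idx <- grid[[key]]
          if (!is.null(idx)) {
            if (any((xs[idx] - px[t])^2 + (ys[idx] - py[t])^2 < separation^2)) {
              ok <- FALSE
              break
            }
          }
        }
        if (!ok) break
      }
      if (ok) {
        accepted <- accepted + 1L
        xs[accepted] <- px[t]
        ys[accepted] <- py[t]
        key <- as.character(cx + cy * ncx)
        grid[[key]] <- c(grid[[key]], accepted)
        if (accepted == n) break
      }
    }
  }
  cbind(x = xs[seq_len(accepted)], y = ys[seq_len(accepted)])
}

#' Generate synthetic audit locations on a featureless plane
#'
#' Emulates the iterative audit-location sampling scheme: uniform random
#' proposals are thinned by a minimum-separation rule, and the separation is
#' adapted across iterations until the mean nearest-neighbor distance falls
#' within one `spacing_sd` of `target_spacing`. The separation starts at
#' 0.6 x the target spacing (a mild hard core whose expected mean spacing at
#' the default density sits near the target) and is scaled by
#' `target / achieved` each round.
#'
#' @param region a [region_spec()].
#' @param max_iter maximum separation adaptations (default 12).
#' @return data.frame `id`, `x`, `y`; attributes `mean_nn`, `sd_nn`,
#'   `separation`, `iterations`, `seed`.
#' @export
generate_locations <- function(region, max_iter = 12L) {
  stopifnot(inherits(region, "region_spec"))
  if (region$n_target == 0L) {
    out <- data.frame(id = character(), x = numeric(), y = numeric())
    attr(out, "mean_nn") <- NA_real_
    return(out)
  }
  sep <- 0.6 * region$target_spacing
  achieved <- NA_real_
  result <- with_seed(region$seed, {
    res <- NULL
    for (it in seq_len(max_iter)) {
      xy <- sample_hardcore(region$n_target, region$extent, sep)
      if (nrow(xy) < region$n_target) {
        ## over-packed: the extent cannot host n_target points at this
        ## separation; relax and retry
        sep <- sep * 0.8
        next
      }
      nn <- nn_distance(xy)
      achieved <- mean(nn)
      if (abs(achieved - region$target_spacing) <= region$spacing_sd) {
        res <- list(xy = xy, nn = nn, it = it)
        break
      }
      sep <- clamp(sep * region$target_spacing / achieved,
                   0.05 * region$target_spacing, 0.95 * region$target_spacing)
    }
    res
  })
  if (is.null(result)) {
    stop(sprintf(
      "location generator did not reach the spacing criterion in %d iterations (achieved mean NN %.1f m, target %.0f +/- %.0f m)",
      max_iter, achieved, region$target_spacing, region$spacing_sd))
  }
  out <- data.frame(id = sprintf("loc%06d", seq_len(nrow(result$xy))),
                    x = result$xy[, 1], y = result$xy[, 2])
  attr(out, "mean_nn") <- mean(result$nn)
  attr(out, "sd_nn") <- stats::sd(result$nn)
  attr(out, "separation") <- sep
  attr(out, "iterations") <- result$it
  attr(out, "seed") <- region$seed
  out
}

#' Simulate a Gaussian random field at fixed points
#'
#' Zero-mean draw whose covariance is `C(h) = total_sill - gamma(h)` for the
#' given nested model, by dense Cholesky factorization with a 1e-8 diagonal
#' jitter. Restricted to models with a finite sill whose covariance is
#' positive definite in the plane (spherical, exponential, Gaussian, Matern,
#' cubic, nugget); sine-hole and power structures are rejected.
#'
#' @param points data.frame with `x`, `y` in meters.
#' @param latent_model a `nested_variogram`.
#' @param seed integer seed.
#' @param max_n dense-factorization cap (default 5000).
#' @return numeric field values, one per point.
#' @export
simulate_latent_field <- function(points, latent_model, seed = 1L,
                                  max_n = 5000L) {
  n <- nrow(points)
  if (n > max_n) {
    stop(sprintf("n = %d exceeds the dense-covariance cap (%d)", n, max_n))
  }
  fams <- vapply(latent_model$structures, `[[`, "", "family")
  if (any(fams %in% c("sine_hole", "power"))) {
    stop("generative covariance restricted to spherical/exponential/gaussian/matern/cubic/nugget structures")
  }
  sill <- total_sill(latent_model)
  if (sill == 0) return(numeric(n))
  xy <- cbind(points$x, points$y) / 1000
  H <- cross_dist(xy, xy)
  C <- sill - matrix(model_semivariance(latent_model, as.vector(H)), n, n)
  diag(C) <- sill + 1e-8
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    stop("covariance not positive definite after jitter for model: ",
         paste(fams, collapse = "-"))
  }
  z <- with_seed(seed, stats::rnorm(n))
  drop(crossprod(U, z))
}

#' Simulation specification for synthetic audit responses
#'
#' The generative model mirrors the analysis model run in reverse: a
#' logit-scale cubic spatial trend plus a rater offset plus a latent
#' spatially autocorrelated field, passed through a Bernoulli draw. The
#' default latent model is a two-scale (nested) structure --- a short-range
#' exponential plus a longer-range spherical component over a small nugget
#' --- and the default rater offsets are `(+0.5, 0, -0.5, 0)` logits for
#' four raters.
#'
#' @param trend_coefficients length-8 vector: intercept then coefficients of
#'   x, y, x^2, y^2, xy, x^3, y^3 on centered kilometer coordinates (logit
#'   scale).
#' @param rater_effects per-rater logit offsets.
#' @param latent_model `nested_variogram` for the latent field.
#' @param prevalence_target optional overall prevalence in (0, 1); when set,
#'   the intercept is re-solved so the mean response probability matches it.
#' @param seed integer seed.
#' @return a `simulation_spec`.
#' @export
simulation_spec <- function(
    trend_coefficients = c(0, 0.12, -0.10, 0.008, -0.006, 0.005,
                           0.0006, -0.0004),
    rater_effects = c(0.5, 0, -0.5, 0),
    latent_model = nested_variogram(
      0.1, list(vgm_structure("exponential", psill = 1.5, range = 0.8),
                vgm_structure("spherical", psill = 0.8, range = 4))),
    prevalence_target = NULL, seed = 1L) {
  if (length(trend_coefficients) != 8L) {
    stop("trend_coefficients must have length 8 (intercept + 7 terms)")
  }
  if (!is.null(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1)) {
    stop("prevalence_target must lie in (0, 1)")
  }
  if (total_sill(latent_model) < 0) stop("latent variance must be >= 0")
  structure(list(trend_coefficients = trend_coefficients,
                 rater_effects = rater_effects,
                 latent_model = latent_model,
                 prevalence_target = prevalence_target,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Assign raters to audit points at random
#'
#' @param n number of points.
#' @param n_raters number of raters (default 4).
#' @param seed integer seed.
#' @return factor of rater labels `r1..rK`.
#' @export
assign_raters <- function(n, n_raters = 4L, seed = 1L) {
  labs <- paste0("r", seq_len(n_raters))
  with_seed(seed, factor(sample(labs, n, replace = TRUE), levels = labs))
}

## logit-scale cubic trend at centered km coordinates
eval_trend_surface <- function(points, coefficients) {
  cx <- (points$x - mean(points$x)) / 1000
  cy <- (points$y - mean(points$y)) / 1000
  X <- cbind(1, cx, cy, cx^2, cy^2, cx * cy, cx^3, cy^3)
  drop(X %*% coefficients)
}

#' Simulate binary audit responses over a latent field
#'
#' Per-point Bernoulli draw with
#' `P(Yes) = plogis(trend(x, y) + rater offset + field)`, stored in the
#' 1 = Yes / 2 = No audit coding.
#'
#' @param points data.frame with `id`, `x`, `y` (an `id` column is created
#'   when absent).
#' @param field latent field values aligned with `points`.
#' @param spec a [simulation_spec()].
#' @param rater_assignment factor of rater labels per point; default
#'   assigned at random from the spec seed.
#' @param item item column name (default `"item_synthetic"`).
#' @return an [audit_dataset()] with one item column; the true Yes
#'   probabilities are kept in `attr(, "true_p")`.
#' @export
simulate_responses <- function(points, field, spec = simulation_spec(),
                               rater_assignment = NULL,
                               item = "item_synthetic") {
  n <- nrow(points)
  if (length(field) != n) stop("field and points are misaligned")
  if (any(!is.finite(field))) stop("latent field contains non-finite values")
  rater_assignment <- rater_assignment %||%
    assign_raters(n, length(spec$rater_effects), derive_seed(spec$seed, "raters"))
  if (length(rater_assignment) != n) stop("rater assignment must cover all points")
  offsets <- spec$rater_effects[as.integer(rater_assignment)]
  eta <- eval_trend_surface(points, spec$trend_coefficients) + offsets + field
  if (!is.null(spec$prevalence_target)) {
    shift <- stats::uniroot(
      function(c0) mean(stats::plogis(eta + c0)) - spec$prevalence_target,
      interval = c(-40, 40))$root
    eta <- eta + shift
  }
  p <- stats::plogis(eta)
  yes <- with_seed(derive_seed(spec$seed, "bernoulli"),
                   stats::rbinom(n, 1L, p))
  df <- data.frame(id = points$id %||% sprintf("loc%06d", seq_len(n)),
                   x = points$x, y = points$y,
                   rater = rater_assignment)
  df[[item]] <- ifelse(yes == 1L, 1, 2)
  out <- audit_dataset(df)
  attr(out, "true_p") <- p
  out
}

#' Generate a synthetic block-group layer with correlated covariates
#'
#' Tiles the extent into `n_units` rectangles (row bands split into
#' columns, an exact tiling) and draws census-style covariates with a
#' configured correlation to the unit-mean latent field.
#'
#' @param region a [region_spec()] (only the extent is used).
#' @param n_units number of units (default 671).
#' @param covariate_spec data.frame with `name`, `latent_correlation`,
#'   `mean`, `sd`; the default emulates racial-ethnic composition,
#'   residential mobility, housing-value and density variables.
#' @param points,latent_field optional audit points and field values used to
#'   form the unit-mean latent signal; units without points (or when
#'   omitted) use an independent standard-normal unit effect.
#' @param seed integer seed.
#' @return a [block_group_layer()]; the standardized unit-mean latent signal
#'   is kept in `attr(, "unit_latent")`.
#' @export
generate_block_groups <- function(region, n_units = 671L,
                                  covariate_spec = NULL,
                                  points = NULL, latent_field = NULL,
                                  seed = 1L) {
  if (n_units < 1L) stop("n_units must be >= 1")
  if (!is.null(points) && n_units > nrow(points)) {
    warning("more block groups than audit points; some units have no points")
  }
  covariate_spec <- covariate_spec %||% data.frame(
    name = c("pct_non_hispanic_white", "pct_non_hispanic_aa", "pct_latinx",
             "pct_recent_movers", "pct_walk_to_work", "median_home_value",
             "median_gross_rent", "population_density"),
    latent_correlation = c(-0.8, 0.7, 0.3, 0.35, 0.4, -0.6, -0.5, 0.5),
    mean = c(45, 30, 20, 12, 5, 350000, 1100, 5000),
    sd = c(25, 25, 15, 6, 4, 120000, 300, 4000))
  ext <- region$extent
  rows <- max(1L, floor(sqrt(n_units)))
  base <- n_units %/% rows
  extra <- n_units %% rows
  ncols <- rep(base, rows) + c(rep(1L, extra), rep(0L, rows - extra))
  ys <- seq(ext[3], ext[4], length.out = rows + 1L)
  tiles <- do.call(rbind, lapply(seq_len(rows), function(r) {
    xs <- seq(ext[1], ext[2], length.out = ncols[r] + 1L)
    data.frame(xmin = xs[-length(xs)], xmax = xs[-1L],
               ymin = ys[r], ymax = ys[r + 1L])
  }))
  tiles$unit <- seq_len(n_units)

  ## unit-mean latent signal, standardized
  z <- with_seed(derive_seed(seed, "unit_latent"), stats::rnorm(n_units))
  if (!is.null(points) && !is.null(latent_field)) {
    row_band <- pmin(pmax(findInterval(points$y, ys, rightmost.closed = TRUE),
                          1L), rows)
    unit_of_point <- integer(nrow(points))
    offset <- c(0L, cumsum(ncols))
    for (r in seq_len(rows)) {
      sel <- row_band == r
      if (!any(sel)) next
      xs <- seq(ext[1], ext[2], length.out = ncols[r] + 1L)
      col <- pmin(pmax(findInterval(points$x[sel], xs, rightmost.closed = TRUE),
                       1L), ncols[r])
      unit_of_point[sel] <- offset[r] + col
    }
    means <- tapply(latent_field, factor(unit_of_point, levels = seq_len(n_units)),
                    mean)
    have <- !is.na(means)
    if (sum(have) > 2L && stats::sd(means[have]) > 0) {
      z[have] <- (means[have] - mean(means[have])) / stats::sd(means[have])
    }
  }
  covs <- with_seed(derive_seed(seed, "covariates"), {
    out <- list()
    for (i in seq_len(nrow(covariate_spec))) {
      rho <- covariate_spec$latent_correlation[i]
      noise <- stats::rnorm(n_units)
      zc <- rho * z + sqrt(1 - rho^2) * noise
      out[[covariate_spec$name[i]]] <-
        covariate_spec$mean[i] + covariate_spec$sd[i] * zc
    }
    out
  })
  layer <- block_group_layer(cbind(tiles[, c("unit", "xmin", "xmax",
                                             "ymin", "ymax")],
                                   as.data.frame(covs)))
  attr(layer, "unit_latent") <- z
  layer
}
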