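#' Specify the large-scale detrending model
#'
#' Detrending fits a logistic regression of the binary item response on a
#' centered polynomial in the planar coordinates, optionally plus rater
#' dummies. The default spatial term set is the seven-term cubic
#' \{x, y, x^2, y^2, xy, x^3, y^3\}; `terms = "cubic9"` selects the full
#' nine-term cubic (adding x^2 y and x y^2). Coordinates are centered at
#' their means and expressed in kilometers before the polynomial expansion,
#' which keeps the cubic columns well-conditioned.
#'
#' @param terms `"cubic7"` (default), `"cubic9"`, or a list of
#'   `c(power_x, power_y)` integer pairs with total degree at most 3.
#' @param include_rater add rater dummy columns (reference level absorbs the
#'   intercept).
#' @param rater_reference reference rater level; default last level.
#' @return a `trend_spec` object.
#' @export
trend_spec <- function(terms = "cubic7", include_rater = FALSE,
                       rater_reference = NULL) {
  if (is.character(terms)) {
    terms <- switch(match.arg(terms, c("cubic7", "cubic9")),
      cubic7 = list(c(1, 0), c(0, 1), c(2, 0), c(0, 2), c(1, 1), c(3, 0), c(0, 3)),
      cubic9 = list(c(1, 0), c(0, 1), c(2, 0), c(0, 2), c(1, 1), c(3, 0), c(0, 3),
                    c(2, 1), c(1, 2)))
  }
  if (!length(terms)) stop("term list must be non-empty")
  for (t in terms) {
    if (length(t) != 2L || any(t < 0) || sum(t) > 3L) {
      stop("each term must be c(power_x, power_y) with total degree <= 3")
    }
  }
  structure(list(terms = terms, include_rater = include_rater,
                 rater_reference = rater_reference),
            class = "trend_spec")
}

term_label <- function(t) {
  p <- function(v, s) if (v == 0) "" else if (v == 1) s else paste0(s, v)
  lab <- paste0(p(t[1], "x"), p(t[2], "y"))
  if (lab == "") "1" else lab
}

#' Build the detrending design matrix
#'
#' Centers coordinates at their means, converts to kilometers, expands the
#' polynomial terms and appends rater dummies when requested.
#'
#' @param dataset an [audit_dataset()] (or any data.frame with `x`, `y` and,
#'   when rater adjustment is requested, `rater`).
#' @param spec a [trend_spec()].
#' @param center optional `c(x, y)` centering constants in meters; defaults
#'   to the column means (stored so the same centering is reused at scoring).
#' @param rater_levels optional rater level vector, reference level first
#'   (as stored on a fitted model); when supplied the dummy coding reuses it
#'   instead of re-deriving the reference from the data.
#' @return list with `X` (matrix incl. intercept), `center`, `rater_levels`.
#' @export
build_design <- function(dataset, spec = trend_spec(), center = NULL,
                         rater_levels = NULL) {
  fitting <- is.null(center)   # scoring passes the stored centering constants
  if (fitting &&
      (nrow(dataset) < 2L || length(unique(paste(dataset$x, dataset$y))) < 2L)) {
    stop("need at least 2 distinct locations")
  }
  center <- center %||% c(mean(dataset$x), mean(dataset$y))
  cx <- (dataset$x - center[1]) / 1000   # km
  cy <- (dataset$y - center[2]) / 1000
  if (fitting && (stats::sd(cx) == 0 || stats::sd(cy) == 0)) {
    warning("a coordinate column is constant; design is rank-deficient")
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(dataset)))
  for (t in spec$terms) {
    X <- cbind(X, cx^t[1] * cy^t[2])
    colnames(X)[ncol(X)] <- term_label(t)
  }
  if (isTRUE(spec$include_rater)) {
    if (is.null(rater_levels)) {
      r <- factor(dataset$rater)
      ref <- spec$rater_reference %||% levels(r)[nlevels(r)]
      if (!ref %in% levels(r)) stop("rater_reference not a rater level")
      r <- stats::relevel(r, ref = ref)
    } else {
      r <- factor(dataset$rater, levels = rater_levels)
      if (anyNA(r)) stop("rater level(s) outside the model's levels")
    }
    if (nlevels(r) > 1L) {
      D <- stats::model.matrix(~r)[, -1L, drop = FALSE]
      colnames(D) <- paste0("rater", levels(r)[-1L])
      X <- cbind(X, D)
    }
    rater_levels <- levels(r)   # first element is the reference
  } else {
    rater_levels <- NULL
  }
  list(X = X, center = center, rater_levels = rater_levels)
}

#' Fit the logistic spatial trend for one item
#'
#' Maximum-likelihood logistic regression of the item's 0/1 response on the
#' centered polynomial (and rater dummies when the spec asks for them).
#' Missing responses are dropped; the item must show both classes.
#'
#' @param dataset an [audit_dataset()].
#' @param item item column name.
#' @param spec a [trend_spec()].
#' @return a `trend_model` with coefficients, centering constants, rater
#'   levels, residual deviance and a convergence flag.
#' @export
fit_trend <- function(dataset, item, spec = trend_spec()) {
  if (!item %in% names(dataset)) stop("unknown item: ", item)
  y <- recode_response(dataset[[item]])
  keep <- !is.na(y)
  d <- dataset[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop(sprintf("item '%s' has a single response class; cannot fit", item))
  }
  des <- build_design(d, spec)
  fit <- suppressWarnings(
    stats::glm.fit(des$X, y, family = stats::binomial()))
  if (!fit$converged) {
    stop(sprintf("logistic fit for item '%s' did not converge (possible separation)",
                 item))
  }
  p <- fit$fitted.values
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    warning(sprintf("item '%s': fitted probabilities at the boundary (quasi-separation)",
                    item))
  }
  structure(list(
    item = item,
    coefficients = stats::coef(fit),
    spec = spec,
    center = des$center,
    rater_levels = des$rater_levels,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    converged = fit$converged,
    n = length(y),
    ids = d$id
  ), class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("trend_model for '%s': %d obs, %d coefficients%s, deviance %.2f\n",
              x$item, x$n, length(x$coefficients),
              if (is.null(x$rater_levels)) "" else " (rater-adjusted)",
              x$deviance))
  invisible(x)
}

#' Score the fitted trend at locations
#'
#' @param model a `trend_model`.
#' @param locations data.frame with `x`, `y` in meters (and `rater` when the
#'   model is rater-adjusted and `rater` is not supplied separately).
#' @param rater optional rater level(s) to score at; for rater-adjusted
#'   models, unknown levels raise an error unless `fallback_reference = TRUE`.
#' @param fallback_reference score unseen rater levels at the reference.
#' @return probability of Yes at each location, in (0, 1).
#' @export
score_trend <- function(model, locations, rater = NULL,
                        fallback_reference = FALSE) {
  d <- as.data.frame(locations)
  if (!is.null(model$rater_levels)) {
    r <- rater %||% d$rater
    if (is.null(r)) stop("rater-adjusted model needs rater levels to score")
    r <- as.character(rep_len(r, nrow(d)))
    unseen <- !(r %in% model$rater_levels)
    if (any(unseen)) {
      if (!fallback_reference) {
        stop("unseen rater level(s): ",
             paste(unique(r[unseen]), collapse = ", "))
      }
      r[unseen] <- model$rater_levels[1L]
    }
    d$rater <- factor(r, levels = model$rater_levels)
  }
  des <- build_design(d, model$spec, center = model$center,
                      rater_levels = model$rater_levels)
  eta <- drop(des$X %*% model$coefficients)
  stats::plogis(eta)
}

#' Deviance residuals of a fitted trend
#'
#' For binary y and fitted probability p, the deviance residual is
#' `sign(y - p) * sqrt(-2 * (y log p + (1 - y) log(1 - p)))`. Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` (with a warning when clamping bites)
#' so residuals stay finite. The residual field carries location ids and
#' coordinates and is the input to semivariography and Kriging.
#'
#' @param model a `trend_model`.
#' @param dataset the dataset the model was fitted on (or any audit dataset
#'   with the item observed).
#' @return data.frame of class `residual_field`: `id`, `x`, `y`, `residual`.
#' @export
deviance_residuals <- function(model, dataset) {
  y <- recode_response(dataset[[model$item]])
  keep <- !is.na(y)
  d <- dataset[keep, , drop = FALSE]
  y <- y[keep]
  p <- score_trend(model, d)
  if (any(p <= 1e-12) || any(p >= 1 - 1e-12)) {
    warning("fitted probabilities clamped to [1e-12, 1 - 1e-12] for deviance")
  }
  p <- clamp(p, 1e-12, 1 - 1e-12)
  eps <- sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p)))
  out <- data.frame(id = d$id, x = d$x, y = d$y, residual = eps)
  class(out) <- c("residual_field", "data.frame")
  out
}

#' Serialize a trend model to JSON
#'
#' @param model a `trend_model`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
trend_to_json <- function(model, path = NULL) {
  obj <- list(
    item = model$item,
    coefficients = as.list(model$coefficients),
    terms = lapply(model$spec$terms, as.integer),
    include_rater = isTRUE(model$spec$include_rater),
    center = model$center,
    rater_levels = model$rater_levels,
    deviance = model$deviance
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a trend model from JSON
#'
#' @param path path to a JSON file written by [trend_to_json()], or a JSON
#'   string.
#' @return a `trend_model`.
#' @export
trend_from_json <- function(path) {
  obj <- if (file.exists(path)) jsonlite::read_json(path) else jsonlite::parse_json(path)
  spec <- trend_spec(terms = lapply(obj$terms, unlist),
                     include_rater = isTRUE(obj$include_rater))
  structure(list(
    item = obj$item,
    coefficients = unlist(obj$coefficients),
    spec = spec,
    center = unlist(obj$center),
    rater_levels = if (is.null(obj$rater_levels)) NULL else unlist(obj$rater_levels),
    deviance = obj$deviance,
    converged = TRUE,
    n = NA_integer_
  ), class = "trend_model")
}
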