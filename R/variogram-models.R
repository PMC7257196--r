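## Theoretical semivariogram families.
##
## All ranges are in kilometers. Bounded families (spherical, cubic) reach
## the partial sill exactly at the range; exponential, Gaussian and Matern
## use the scale-parameter convention gamma(h) = c * (1 - rho(h / a)) and
## approach the sill asymptotically. The sine-hole (wave) model is
## c * (1 - sin(pi h / a) / (pi h / a)); the power model is b * h^p with
## p in (0, 2] and has no sill.

VGM_FAMILIES <- c("nugget", "spherical", "exponential", "gaussian",
                  "matern", "cubic", "sine_hole", "power")

#' A single theoretical semivariogram structure
#'
#' @param family one of `"nugget"`, `"spherical"`, `"exponential"`,
#'   `"gaussian"`, `"matern"`, `"cubic"`, `"sine_hole"`, `"power"`.
#' @param psill partial sill (for `"power"`: the coefficient *b*).
#' @param range range parameter in km (for `"power"`: the exponent *p*,
#'   which must lie in (0, 2]).
#' @param kappa Matern smoothness (only used by `"matern"`), default 0.5.
#' @return a `vgm_structure`.
#' @export
vgm_structure <- function(family, psill, range = NA_real_, kappa = 0.5) {
  family <- match.arg(family, VGM_FAMILIES)
  if (psill < 0) stop("partial sill must be >= 0")
  if (family == "power") {
    if (!is.finite(range) || range <= 0 || range > 2) {
      stop("power exponent p must lie in (0, 2]")
    }
  } else if (family != "nugget") {
    if (!is.finite(range) || range <= 0) stop("range must be > 0")
  }
  structure(list(family = family, psill = psill, range = range, kappa = kappa),
            class = "vgm_structure")
}

## semivariance contribution of one structure at distances h (km), h >= 0
structure_gamma <- function(s, h) {
  c0 <- s$psill
  a <- s$range
  g <- switch(s$family,
    nugget = c0 * as.numeric(h > 0),
    spherical = {
      t <- pmin(h / a, 1)
      c0 * (1.5 * t - 0.5 * t^3)
    },
    exponential = c0 * (1 - exp(-h / a)),
    gaussian = c0 * (1 - exp(-(h / a)^2)),
    matern = {
      t <- h / a
      rho <- rep(1, length(t))
      pos <- t > 0
      tp <- t[pos]
      rho[pos] <- (2^(1 - s$kappa) / gamma(s$kappa)) * tp^s$kappa *
        besselK(tp, s$kappa)
      ## numeric underflow at large t: correlation -> 0
      rho[!is.finite(rho)] <- 0
      c0 * (1 - rho)
    },
    cubic = {
      t <- pmin(h / a, 1)
      c0 * (7 * t^2 - 8.75 * t^3 + 3.5 * t^5 - 0.75 * t^7)
    },
    sine_hole = {
      t <- pi * h / a
      out <- rep(0, length(t))
      pos <- t > 0
      out[pos] <- c0 * (1 - sin(t[pos]) / t[pos])
      out
    },
    power = c0 * h^a   # psill = b, range slot holds the exponent p
  )
  g
}

#' A nugget plus up to two theoretical structures
#'
#' @param nugget nugget variance, `>= 0`.
#' @param structures list of 1-2 [vgm_structure()] objects (a single
#'   structure may be passed bare).
#' @param sse optional weighted SSE recorded by the fitting routine.
#' @param item,detrending optional provenance labels.
#' @return a `nested_variogram`.
#' @export
nested_variogram <- function(nugget, structures, sse = NA_real_,
                             item = NA_character_, detrending = NA_character_) {
  if (nugget < 0) stop("nugget must be >= 0")
  if (inherits(structures, "vgm_structure")) structures <- list(structures)
  if (!length(structures) || length(structures) > 2L) {
    stop("need 1 or 2 structures")
  }
  structure(list(nugget = nugget, structures = structures, sse = sse,
                 item = item, detrending = detrending),
            class = "nested_variogram")
}

#' Total sill of a nested model
#'
#' Nugget plus the sum of partial sills; `NA` when any structure is a power
#' model (no finite sill).
#'
#' @param model a `nested_variogram`.
#' @return numeric.
#' @export
total_sill <- function(model) {
  fams <- vapply(model$structures, `[[`, "", "family")
  if (any(fams == "power")) return(NA_real_)
  model$nugget + sum(vapply(model$structures, `[[`, 0, "psill"))
}

#' Evaluate a nested theoretical semivariogram
#'
#' `gamma(0) = 0` exactly; the limit from the right is the nugget.
#'
#' @param model a `nested_variogram`.
#' @param h distances in km, `>= 0`.
#' @return semivariances at `h`.
#' @export
model_semivariance <- function(model, h) {
  if (any(h < 0)) stop("negative lag distance")
  g <- model$nugget * as.numeric(h > 0)
  for (s in model$structures) g <- g + structure_gamma(s, h)
  g
}

#' Effective range of a nested model
#'
#' Smallest distance at which the model reaches 95% of its sill above the
#' nugget (evaluated on a dense grid up to `max_lag`); `max_lag` for power
#' models and other non-saturating cases.
#'
#' @param model a `nested_variogram`.
#' @param max_lag grid upper bound in km.
#' @return distance in km.
#' @export
effective_range <- function(model, max_lag) {
  sill <- total_sill(model)
  if (is.na(sill)) return(max_lag)
  if (sill <= model$nugget) return(0)
  h <- seq(0, max_lag, length.out = 512L)[-1L]
  g <- model_semivariance(model, h)
  target <- model$nugget + 0.95 * (sill - model$nugget)
  idx <- which(g >= target)
  if (!length(idx)) max_lag else h[idx[1L]]
}

#' @export
print.nested_variogram <- function(x, ...) {
  desc <- vapply(x$structures, function(s) {
    if (s$family == "power") {
      sprintf("power(b=%.4g, p=%.3g)", s$psill, s$range)
    } else if (s$family == "matern") {
      sprintf("matern(psill=%.4g, range=%.4g km, kappa=%.2g)",
              s$psill, s$range, s$kappa)
    } else {
      sprintf("%s(psill=%.4g, range=%.4g km)", s$family, s$psill, s$range)
    }
  }, "")
  cat(sprintf("nested_variogram: nugget %.4g + %s", x$nugget,
              paste(desc, collapse = " + ")))
  if (is.finite(x$sse)) cat(sprintf("  [wSSE %.4g]", x$sse))
  cat("\n")
  invisible(x)
}
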