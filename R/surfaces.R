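#' Leave-one-out likelihood cross-validation of a kernel bandwidth
#'
#' For each candidate bandwidth (meters) of an isotropic Gaussian kernel,
#' the leave-one-out kernel-weighted probability estimate at every point is
#' scored by the negative Bernoulli log-likelihood; the candidate minimizing
#' the total is returned (ties go to the smaller bandwidth). Probabilities
#' are clipped to `[1e-6, 1 - 1e-6]` inside the likelihood.
#'
#' @param points data.frame with `x`, `y` in meters.
#' @param y 0/1 responses.
#' @param candidates candidate bandwidths in meters; default 16 log-spaced
#'   values from the mean nearest-neighbor distance to a quarter of the
#'   extent diagonal.
#' @return the selected bandwidth; candidate objective values in
#'   `attr(, "objective")`.
#' @export
cv_bandwidth <- function(points, y, candidates = NULL) {
  n <- nrow(points)
  if (n < 10L) stop("need at least 10 points")
  if (length(unique(y)) < 2L) stop("both response classes must be present")
  if (is.null(candidates)) {
    lo <- mean(nn_distance(cbind(points$x, points$y)))
    hi <- sqrt(diff(range(points$x))^2 + diff(range(points$y))^2) / 4
    candidates <- exp(seq(log(lo), log(hi), length.out = 16L))
  }
  d2 <- cross_dist(cbind(points$x, points$y), cbind(points$x, points$y))^2
  obj <- vapply(candidates, function(b) {
    W <- exp(-d2 / (2 * b^2))
    diag(W) <- 0                     # leave-one-out
    denom <- rowSums(W)
    if (any(denom <= 0)) return(Inf)
    p <- clamp(rowSums(W * rep(y, each = n)) / denom, 1e-6, 1 - 1e-6)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }, 0)
  if (all(!is.finite(obj))) stop("all candidate bandwidths are degenerate")
  ord <- order(obj, candidates)     # ties -> smaller bandwidth
  out <- candidates[ord[1L]]
  attr(out, "objective") <- data.frame(bandwidth = candidates, nll = obj)
  out
}

#' Nonparametric spatially varying probability surface
#'
#' Nadaraya-Watson ratio of Gaussian-kernel-weighted Yes-mass to total mass
#' on a regular grid. Cells whose total kernel weight falls below
#' `min_weight` are set to the overall prevalence (the far-field fallback).
#'
#' @param points data.frame with `x`, `y` in meters.
#' @param y 0/1 responses.
#' @param bandwidth kernel bandwidth in meters.
#' @param resolution grid cell size in meters (default extent/64).
#' @param extent `c(xmin, xmax, ymin, ymax)`; default the point bounding box.
#' @param min_weight minimum total kernel weight per cell (default 1e-3).
#' @return data.frame of class `probability_surface` with `x`, `y`, `p`;
#'   attributes `bandwidth`, `prevalence`, `resolution`.
#' @export
probability_surface <- function(points, y, bandwidth, resolution = NULL,
                                extent = NULL, min_weight = 1e-3) {
  if (!nrow(points)) stop("empty point set")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  extent <- extent %||% c(range(points$x), range(points$y))
  resolution <- resolution %||% max(extent[2] - extent[1],
                                    extent[4] - extent[3]) / 64
  gx <- seq(extent[1] + resolution / 2, extent[2], by = resolution)
  gy <- seq(extent[3] + resolution / 2, extent[4], by = resolution)
  grid <- expand.grid(x = gx, y = gy)
  prevalence <- mean(y)
  p <- numeric(nrow(grid))
  block <- 2048L
  for (i0 in seq(1L, nrow(grid), by = block)) {
    i1 <- min(i0 + block - 1L, nrow(grid))
    W <- exp(-cross_dist(grid[i0:i1, ], cbind(points$x, points$y))^2 /
               (2 * bandwidth^2))
    tot <- rowSums(W)
    yes <- drop(W %*% y)
    pb <- ifelse(tot < min_weight, prevalence, yes / pmax(tot, 1e-300))
    p[i0:i1] <- pb
  }
  out <- data.frame(grid, p = p)
  class(out) <- c("probability_surface", "data.frame")
  attr(out, "bandwidth") <- bandwidth
  attr(out, "prevalence") <- prevalence
  attr(out, "resolution") <- resolution
  out
}

#' Render a probability surface with a divergent palette
#'
#' Diverging red/white/blue shading anchored so that white equals the item's
#' overall prevalence: red cells are above-average probability of Yes, blue
#' below-average.
#'
#' @param surface a [probability_surface()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
render_divergent <- function(surface, title = NULL) {
  prev <- attr(surface, "prevalence")
  ggplot2::ggplot(surface, ggplot2::aes(x = x, y = y, fill = p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", midpoint = prev,
                                  limits = c(0, 1),
                                  name = sprintf("P(Yes)\nwhite = %.3f", prev)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
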