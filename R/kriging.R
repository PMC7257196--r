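#' Local ordinary Kriging neighborhood rules
#'
#' Training points within `radius_km` of the target are used; when fewer
#' than `min_neighbors` fall inside the radius, the nearest `min_neighbors`
#' points are used regardless of radius (the radius actually used is
#' recorded per prediction).
#'
#' @param radius_km search radius in km (default 1.3).
#' @param min_neighbors minimum neighbor count (default 30).
#' @param max_neighbors optional cap on the neighbor count (nearest first).
#' @return a `kriging_plan`.
#' @export
kriging_plan <- function(radius_km = 1.3, min_neighbors = 30L,
                         max_neighbors = NULL) {
  stopifnot(radius_km > 0, min_neighbors >= 1L)
  structure(list(radius_km = radius_km, min_neighbors = as.integer(min_neighbors),
                 max_neighbors = if (is.null(max_neighbors)) NULL
                                 else as.integer(max_neighbors)),
            class = "kriging_plan")
}

#' Select the Kriging neighborhood for one target location
#'
#' @param target `c(x, y)` in meters.
#' @param train data.frame with `x`, `y` in meters.
#' @param plan a [kriging_plan()].
#' @return list with `index` (row indices into `train`, ordered by
#'   distance), `dist_km`, `radius_used_km`, `exhausted` (TRUE when the
#'   whole training set was smaller than `min_neighbors`).
#' @export
select_neighbors <- function(target, train, plan = kriging_plan()) {
  if (!nrow(train)) stop("no training points")
  d_km <- sqrt((train$x - target[1])^2 + (train$y - target[2])^2) / 1000
  ord <- order(d_km)
  inside <- which(d_km <= plan$radius_km)
  exhausted <- FALSE
  if (length(inside) >= plan$min_neighbors) {
    idx <- ord[seq_len(length(inside))]
    radius_used <- plan$radius_km
  } else if (nrow(train) >= plan$min_neighbors) {
    idx <- ord[seq_len(plan$min_neighbors)]
    radius_used <- d_km[idx[length(idx)]]
  } else {
    idx <- ord
    radius_used <- d_km[idx[length(idx)]]
    exhausted <- TRUE
  }
  if (!is.null(plan$max_neighbors) && length(idx) > plan$max_neighbors) {
    idx <- idx[seq_len(plan$max_neighbors)]
    radius_used <- min(radius_used, d_km[idx[length(idx)]])
  }
  list(index = idx, dist_km = d_km[idx], radius_used_km = radius_used,
       exhausted = exhausted)
}

## Average co-located points (identical coordinates) before solving; OK
## systems with duplicated rows are singular.
dedupe_colocated <- function(field) {
  key <- paste(field$x, field$y, sep = "_")
  if (!anyDuplicated(key)) return(field)
  agg <- stats::aggregate(field$residual, list(key = key), mean)
  first <- !duplicated(key)
  out <- field[first, , drop = FALSE]
  out$residual <- agg$x[match(key[first], agg$key)]
  out
}

#' Ordinary Kriging prediction at one location
#'
#' Solves the OK system in semivariogram form (so models without a finite
#' sill, e.g. power structures, are handled directly):
#' `[Gamma 1; 1' 0] [w; mu] = [gamma0; 1]`, prediction `sum w_i e_i`,
#' variance `w' gamma0 + mu`. Near-singular systems fall back to a
#' least-squares pseudo-solve.
#'
#' @param target `c(x, y)` in meters.
#' @param neighbors data.frame with `x`, `y` (meters) and `residual`.
#' @param model a `nested_variogram`.
#' @return list `pred`, `var`, `weights`, `n_neighbors`.
#' @export
krige_point <- function(target, neighbors, model) {
  neighbors <- dedupe_colocated(neighbors)
  n <- nrow(neighbors)
  if (n < 2L) stop("need at least 2 distinct neighbors")
  xy <- cbind(neighbors$x, neighbors$y) / 1000
  G <- cross_dist(xy, xy)
  G[] <- model_semivariance(model, as.vector(G))
  diag(G) <- 0
  g0 <- sqrt((xy[, 1] - target[1] / 1000)^2 + (xy[, 2] - target[2] / 1000)^2)
  g0 <- model_semivariance(model, g0)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    sol <- stats::lm.fit(A, b)$coefficients
    sol[!is.finite(sol)] <- 0
    sol <- sol + (1 - sum(sol[seq_len(n)])) / n * c(rep(1, n), 0)
  }
  w <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  pred <- sum(w * neighbors$residual)
  v <- sum(w * g0) + mu
  list(pred = pred, var = max(v, 0), weights = w, n_neighbors = n)
}

#' Local ordinary Kriging over a validation set
#'
#' One prediction per validation location using the neighborhood rules of
#' the plan; deterministic given its inputs.
#'
#' @param validation data.frame with `id`, `x`, `y` (meters).
#' @param train_field data.frame with `id`, `x`, `y`, `residual` (e.g. a
#'   `residual_field`); ids must be disjoint from the validation ids.
#' @param model a `nested_variogram`.
#' @param plan a [kriging_plan()].
#' @return data.frame: `id`, `predicted_residual`, `kriging_variance`,
#'   `n_neighbors`, `radius_used_km`.
#' @export
krige_field <- function(validation, train_field, model, plan = kriging_plan()) {
  if (length(intersect(validation$id, train_field$id))) {
    stop("training and validation ids overlap")
  }
  train_field <- dedupe_colocated(train_field)
  n <- nrow(validation)
  out <- data.frame(id = validation$id,
                    predicted_residual = numeric(n),
                    kriging_variance = numeric(n),
                    n_neighbors = integer(n),
                    radius_used_km = numeric(n))
  for (i in seq_len(n)) {
    tgt <- c(validation$x[i], validation$y[i])
    nb <- select_neighbors(tgt, train_field, plan)
    kv <- tryCatch(
      krige_point(tgt, train_field[nb$index, , drop = FALSE], model),
      error = function(e) {
        stop(sprintf("kriging failed at id '%s': %s",
                     validation$id[i], conditionMessage(e)))
      })
    out$predicted_residual[i] <- kv$pred
    out$kriging_variance[i] <- kv$var
    out$n_neighbors[i] <- kv$n_neighbors
    out$radius_used_km[i] <- nb$radius_used_km
  }
  out
}
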