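utils::globalVariables(c("x", "y", "p", "value"))

#' Construct a block-group layer of rectangular tiles
#'
#' Units are axis-aligned rectangles (`xmin`, `xmax`, `ymin`, `ymax`,
#' meters) that tile the study extent without overlap, with one row per
#' unit plus covariate columns.
#'
#' @param df data.frame with `unit`, `xmin`, `xmax`, `ymin`, `ymax` and
#'   covariate columns.
#' @return the validated data.frame with class `block_group_layer`.
#' @export
block_group_layer <- function(df) {
  req <- c("unit", "xmin", "xmax", "ymin", "ymax")
  if (length(miss <- setdiff(req, names(df)))) {
    stop("block-group layer missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$xmax <= df$xmin) || any(df$ymax <= df$ymin)) {
    stop("degenerate unit rectangles")
  }
  covs <- setdiff(names(df), req)
  for (cv in covs) {
    if (is.numeric(df[[cv]]) && any(!is.finite(df[[cv]]))) {
      stop("non-finite covariate values in: ", cv)
    }
  }
  class(df) <- c("block_group_layer", "data.frame")
  attr(df, "covariates") <- covs
  df
}

#' Sample prediction points uniformly within each block group
#'
#' Exactly `k` points uniformly inside each unit rectangle, tagged by unit
#' and imputation index 1..k; reproducible under the seed.
#'
#' @param layer a [block_group_layer()].
#' @param k points per unit (default 10).
#' @param seed integer seed.
#' @return data.frame: `id`, `unit`, `imp`, `x`, `y`.
#' @export
sample_prediction_points <- function(layer, k = 10L, seed = 1L) {
  if (k == 0L) {
    return(data.frame(id = character(), unit = integer(), imp = integer(),
                      x = numeric(), y = numeric()))
  }
  n <- nrow(layer)
  with_seed(seed, {
    x <- stats::runif(n * k, rep(layer$xmin, each = k), rep(layer$xmax, each = k))
    y <- stats::runif(n * k, rep(layer$ymin, each = k), rep(layer$ymax, each = k))
  })
  unit <- rep(layer$unit, each = k)
  imp <- rep(seq_len(k), times = n)
  data.frame(id = sprintf("bg%s_%d", unit, imp), unit = unit, imp = imp,
             x = x, y = y)
}

fisher_z <- function(r) atanh(clamp(r, -1 + 1e-12, 1 - 1e-12))

#' Pool a correlation across imputations by Rubin's rules on the Fisher scale
#'
#' Per-imputation Pearson correlations across block groups are Fisher-z
#' transformed; the pooled z is the imputation mean, the total variance is
#' the within-imputation variance `1/(n-3)` plus `(1 + 1/m)` times the
#' between-imputation variance, and the pooled z is back-transformed to r.
#'
#' @param table data.frame with columns `unit`, `imp`, and the two
#'   variables; one row per unit x imputation (covariates constant within
#'   unit are fine).
#' @param var1,var2 column names.
#' @return list: `pooled_r`, `pooled_z`, `within_var`, `between_var`,
#'   `total_var`, `m`, `n_units`.
#' @export
pooled_correlation <- function(table, var1, var2) {
  imps <- sort(unique(table$imp))
  m <- length(imps)
  if (m < 2L) stop("need at least 2 imputations")
  rs <- vapply(imps, function(i) {
    d <- table[table$imp == i, ]
    if (nrow(d) < 3L) stop("need at least 3 block groups")
    if (stats::sd(d[[var1]]) == 0 || stats::sd(d[[var2]]) == 0) {
      return(NA_real_)
    }
    stats::cor(d[[var1]], d[[var2]])
  }, 0)
  if (sum(is.na(rs)) > m / 2) {
    stop(sprintf("correlation undefined in %d of %d imputations (%s ~ %s)",
                 sum(is.na(rs)), m, var1, var2))
  }
  rs <- rs[!is.na(rs)]
  m_used <- length(rs)
  n_units <- length(unique(table$unit))
  z <- fisher_z(rs)
  zbar <- mean(z)
  within <- 1 / (n_units - 3)
  between <- if (m_used > 1L) stats::var(z) else 0
  list(pooled_r = tanh(zbar), pooled_z = zbar,
       within_var = within, between_var = between,
       total_var = within + (1 + 1 / m_used) * between,
       m = m_used, n_units = n_units)
}

#' Pooled correlation matrix over items and covariates
#'
#' Symmetric matrix of Rubin-pooled block-group-level Pearson correlations,
#' with a companion flag matrix marking `|r| > flag_threshold`.
#'
#' @param table as in [pooled_correlation()].
#' @param variables column names to correlate.
#' @param flag_threshold default 0.8.
#' @return list: `r` (matrix), `total_var` (matrix), `flagged` (logical
#'   matrix).
#' @export
correlation_matrix_mi <- function(table, variables, flag_threshold = 0.8) {
  k <- length(variables)
  if (k < 2L) stop("need at least 2 variables")
  R <- diag(1, k); V <- matrix(0, k, k)
  dimnames(R) <- dimnames(V) <- list(variables, variables)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pc <- pooled_correlation(table, variables[i], variables[j])
    R[i, j] <- R[j, i] <- pc$pooled_r
    V[i, j] <- V[j, i] <- pc$total_var
  }
  list(r = R, total_var = V, flagged = abs(R) > flag_threshold & row(R) != col(R))
}

#' Heatmap of a pooled correlation matrix
#'
#' @param cormat result of [correlation_matrix_mi()].
#' @return a ggplot object with a divergent palette.
#' @export
plot_correlation_matrix <- function(cormat) {
  R <- cormat$r
  df <- data.frame(
    x = factor(rep(colnames(R), each = nrow(R)), levels = colnames(R)),
    y = factor(rep(rownames(R), times = ncol(R)), levels = rev(rownames(R))),
    value = as.vector(R))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", midpoint = 0,
                                  limits = c(-1, 1), name = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
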