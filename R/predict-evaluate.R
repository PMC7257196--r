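## Continuous-response binomial deviance: for u in [0, 1] and p in (0, 1),
## d(u, p) = sign(u - p) * sqrt(2 * [u log(u/p) + (1-u) log((1-u)/(1-p))]).
## At binary u this reduces to the usual logistic deviance residual
## sign(y - p) * sqrt(-2 * [y log p + (1-y) log(1-p)]); unlike the naive
## substitution of a fractional y into that formula, it is continuous, zero
## at u = p, and strictly monotone in u, so it has a well-defined inverse.
deviance_continuous <- function(u, p) {
  n <- max(length(u), length(p))
  u <- rep_len(u, n)
  p <- rep_len(p, n)
  term <- function(a, b) {
    out <- numeric(length(a))
    pos <- a > 0
    out[pos] <- a[pos] * log(a[pos] / b[pos])
    out
  }
  val <- 2 * (term(u, p) + term(1 - u, 1 - p))
  sign(u - p) * sqrt(pmax(val, 0))
}

#' Back-transform a kriged deviance residual to a raw (probability) residual
#'
#' Solves for the pseudo-response `u` in `[0, 1]` whose continuous binomial
#' deviance residual at trend probability `p` equals `d` (bisection to
#' 1e-10; `d` is first clamped to the attainable interval
#' `[d(0, p), d(1, p)]`), and returns the raw residual `u - p`. With
#' `mode = "identity"` the kriged value is passed through unchanged on the
#' residual scale (a sensitivity-analysis alternative).
#'
#' @param d kriged deviance residual(s).
#' @param p trend probability(ies) in (0, 1).
#' @param mode `"deviance"` (default) or `"identity"`.
#' @return raw residual(s) `r = u - p` with `sign(r) = sign(d)`.
#' @export
invert_deviance <- function(d, p, mode = c("deviance", "identity")) {
  mode <- match.arg(mode)
  if (any(p <= 0 | p >= 1)) stop("trend probabilities must lie in (0, 1)")
  if (mode == "identity") return(d)
  n <- max(length(d), length(p))
  d <- rep_len(d, n); p <- rep_len(p, n)
  d <- pmax(pmin(d, deviance_continuous(1, p)), deviance_continuous(0, p))
  lo <- ifelse(d >= 0, p, 0)
  hi <- ifelse(d >= 0, 1, p)
  for (k in seq_len(60L)) {
    mid <- (lo + hi) / 2
    f <- deviance_continuous(mid, p) - d
    below <- f < 0
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  u <- (lo + hi) / 2
  ## snap exact fixed point
  u[d == 0] <- p[d == 0]
  u - p
}

#' Assemble final predictions from trend scores and kriged residuals
#'
#' The predicted response probability is the trend probability plus the
#' back-transformed kriged residual, clipped to `[0, 1]`.
#'
#' @param trend data.frame `id`, `p` (trend probability).
#' @param kriged data.frame `id`, `predicted_residual` (deviance scale) as
#'   from [krige_field()].
#' @param observed data.frame `id`, `y` (0/1 observed response).
#' @param mode back-transformation mode, see [invert_deviance()].
#' @return data.frame of `prediction_record`s: `id`, `p_trend`,
#'   `kriged_deviance`, `raw_residual`, `y_hat`, `y_obs`.
#' @export
assemble_predictions <- function(trend, kriged, observed,
                                 mode = c("deviance", "identity")) {
  mode <- match.arg(mode)
  ids <- trend$id
  orphans <- c(setdiff(ids, kriged$id), setdiff(kriged$id, ids),
               setdiff(ids, observed$id))
  if (length(orphans)) {
    stop("id mismatch; orphan ids: ",
         paste(utils::head(unique(orphans), 5L), collapse = ", "))
  }
  k <- kriged[match(ids, kriged$id), ]
  o <- observed[match(ids, observed$id), ]
  p <- clamp(trend$p, 1e-12, 1 - 1e-12)
  r <- invert_deviance(k$predicted_residual, p, mode = mode)
  data.frame(id = ids,
             p_trend = trend$p,
             kriged_deviance = k$predicted_residual,
             raw_residual = r,
             y_hat = clamp(trend$p + r, 0, 1),
             y_obs = o$y)
}

#' Root mean squared prediction error
#'
#' `sqrt(mean((y_obs - y_hat)^2))` over validation records.
#'
#' @param records data.frame with `y_obs` and `y_hat` (or two numeric
#'   vectors via `y_hat`).
#' @param y_hat optional predictions when `records` is the observation
#'   vector.
#' @return RMSPE.
#' @export
rmspe <- function(records, y_hat = NULL) {
  if (is.null(y_hat)) {
    obs <- records$y_obs; pred <- records$y_hat
  } else {
    obs <- records; pred <- y_hat
  }
  if (!length(obs)) stop("no records")
  sqrt(mean((obs - pred)^2))
}

#' ROC AUC as the Mann-Whitney concordance probability
#'
#' Probability that a random positive receives a higher score than a random
#' negative, with ties counted one half (computed from rank sums).
#'
#' @param records data.frame with `y_obs` (0/1) and `y_hat`, or the
#'   observation vector when `scores` is given.
#' @param scores optional score vector.
#' @return AUC in `[0, 1]`; `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(records, scores = NULL) {
  if (is.null(scores)) {
    y <- records$y_obs; s <- records$y_hat
  } else {
    y <- records; s <- scores
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class validation set; AUC undefined")
    return(NA_real_)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`.
#'
#' @param before,after numeric.
#' @return percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("percent change undefined for before = 0")
  100 * (after - before) / before
}

#' Qualitative predictive-accuracy label for a ROC AUC
#'
#' 0.5 is labeled `"None"`; `[0.7, 0.8)` `"Acceptable"`; `[0.8, 0.9)`
#' `"Excellent"`; `>= 0.9` `"Outstanding"`; anything else below 0.7 is
#' `"less than Acceptable"`.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return character label(s).
#' @export
accuracy_label <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) stop("AUC must lie in [0, 1]")
  vapply(auc, function(a) {
    if (is.na(a)) NA_character_
    else if (a == 0.5) "None"
    else if (a >= 0.9) "Outstanding"
    else if (a >= 0.8) "Excellent"
    else if (a >= 0.7) "Acceptable"
    else "less than Acceptable"
  }, "")
}

#' Summarize an item-by-variant results table
#'
#' Computes the headline counts of a full 31-item x 2-variant evaluation:
#' full models at AUC at or above 0.9 and below 0.7, items whose full-model
#' AUC improves with rater adjustment, items with lower rater-adjusted
#' RMSPE, items with lower rater-adjusted nuggets, models whose full
#' (trend + Kriging) AUC beats the trend-only AUC, and group means of the
#' rater percent AUC change (with an optional item exclusion list for
#' outlier sensitivity).
#'
#' @param table2 semivariogram/RMSPE table shaped like
#'   `load_reference_table(2)`: columns `item`, `group`, `detrending`
#'   (`spatial` / `spatial_rater`), `nugget`, `rmspe`, `rmspe_pct_change`.
#' @param table3 AUC table shaped like `load_reference_table(3)`: columns
#'   `item`, `group`, `detrending`, `auc_large`, `auc_full`,
#'   `auc_pct_change_rater`.
#' @param exclude_items items dropped from the group means (not from the
#'   counts).
#' @return named list of summary counts and group means.
#' @export
summarize_results_table <- function(table2, table3, exclude_items = character()) {
  need2 <- c("item", "detrending", "nugget", "rmspe", "rmspe_pct_change")
  need3 <- c("item", "group", "detrending", "auc_large", "auc_full",
             "auc_pct_change_rater")
  if (length(miss <- setdiff(need2, names(table2)))) {
    stop("table2 is missing columns: ", paste(miss, collapse = ", "))
  }
  if (length(miss <- setdiff(need3, names(table3)))) {
    stop("table3 is missing columns: ", paste(miss, collapse = ", "))
  }
  items <- unique(table3$item)
  for (tab in list(table2, table3)) {
    cells <- table(factor(tab$item, levels = items),
                   factor(tab$detrending,
                          levels = c("spatial", "spatial_rater")))
    if (any(cells != 1L)) {
      bad <- rownames(cells)[rowSums(cells != 1L) > 0]
      stop("incomplete table; missing/duplicated cells for: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  rater3 <- table3[table3$detrending == "spatial_rater", ]
  w2 <- merge(table2[table2$detrending == "spatial", c("item", "nugget")],
              table2[table2$detrending == "spatial_rater", c("item", "nugget")],
              by = "item", suffixes = c("_spatial", "_rater"))
  keep <- !(rater3$item %in% exclude_items)
  group_means <- tapply(rater3$auc_pct_change_rater[keep], rater3$group[keep],
                        mean)
  list(
    n_items = length(items),
    n_full_models = nrow(table3),
    full_outstanding = sum(table3$auc_full >= 0.9),
    full_below_acceptable = sum(table3$auc_full < 0.7),
    items_rater_auc_improved = sum(rater3$auc_pct_change_rater > 0),
    items_rater_rmspe_lower = sum(table2$rmspe_pct_change < 0, na.rm = TRUE),
    items_rater_nugget_lower = sum(w2$nugget_rater < w2$nugget_spatial),
    full_beats_large = sum(table3$auc_full > table3$auc_large),
    rater_auc_change_mean = mean(rater3$auc_pct_change_rater[keep]),
    rater_auc_change_group_means = group_means
  )
}
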