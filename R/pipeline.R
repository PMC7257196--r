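#' Configuration for the per-item analysis pipeline
#'
#' Bundles the split fraction, Kriging plan, semivariogram settings and
#' back-transformation mode used by [run_item()] / [run_all()]. All
#' randomness derives from the single master `seed`.
#'
#' @param seed master seed.
#' @param split training fraction in (0, 1), default 0.9.
#' @param plan a [kriging_plan()].
#' @param n_lags,max_lag empirical semivariogram binning (see
#'   [empirical_semivariogram()]).
#' @param families,max_structures,kappa_grid nested WLS candidates (see
#'   [fit_nested_wls()]).
#' @param assess_anisotropy fit the 8 directional semivariograms and
#'   classify anisotropy (default TRUE).
#' @param backtransform `"deviance"` or `"identity"` (see
#'   [invert_deviance()]).
#' @return a `run_config`.
#' @export
run_config <- function(seed = 1L, split = 0.9, plan = kriging_plan(),
                       n_lags = 40L, max_lag = NULL,
                       families = c("spherical", "exponential", "gaussian",
                                    "matern"),
                       max_structures = 2L, kappa_grid = c(0.5, 1, 1.5, 2.5),
                       assess_anisotropy = TRUE,
                       backtransform = c("deviance", "identity")) {
  if (split <= 0 || split >= 1) stop("split fraction must lie in (0, 1)")
  structure(list(seed = as.integer(seed), split = split, plan = plan,
                 n_lags = as.integer(n_lags), max_lag = max_lag,
                 families = families, max_structures = as.integer(max_structures),
                 kappa_grid = kappa_grid,
                 assess_anisotropy = isTRUE(assess_anisotropy),
                 backtransform = match.arg(backtransform)),
            class = "run_config")
}

#' Read/write a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` invisibly ([write_config()]) or a `run_config`
#'   ([read_config()]).
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$plan <- unclass(obj$plan)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = obj$seed, split = obj$split,
             plan = kriging_plan(obj$plan$radius_km, obj$plan$min_neighbors,
                                 obj$plan$max_neighbors),
             n_lags = obj$n_lags, max_lag = obj$max_lag,
             families = obj$families, max_structures = obj$max_structures,
             kappa_grid = obj$kappa_grid,
             assess_anisotropy = obj$assess_anisotropy,
             backtransform = obj$backtransform)
}

## one shared 90-10 split per item so rater/no-rater comparisons are paired
split_train_validation <- function(dataset, item, config) {
  y <- recode_response(dataset[[item]])
  keep <- which(!is.na(y))
  n <- length(keep)
  n_train <- max(2L, round(config$split * n))
  idx <- with_seed(derive_seed(config$seed, paste0("split_", item)),
                   sample(keep, n_train))
  list(train = dataset[sort(idx), , drop = FALSE],
       validation = dataset[setdiff(keep, idx), , drop = FALSE])
}

run_variant <- function(splits, item, include_rater, config) {
  spec <- trend_spec(include_rater = include_rater)
  model <- fit_trend(splits$train, item, spec)
  resid_field <- deviance_residuals(model, splits$train)

  emp <- empirical_semivariogram(resid_field, max_lag = config$max_lag,
                                 n_lags = config$n_lags)
  vgm <- fit_nested_wls(emp, families = config$families,
                        max_structures = config$max_structures,
                        kappa_grid = config$kappa_grid)
  aniso <- NA_character_
  dir_fits <- NULL
  if (config$assess_anisotropy) {
    dir_emps <- directional_semivariograms(resid_field,
                                           max_lag = attr(emp, "max_lag"),
                                           n_lags = config$n_lags)
    dir_fits <- lapply(dir_emps, function(e) {
      tryCatch(fit_nested_wls(e, families = config$families,
                              max_structures = config$max_structures,
                              kappa_grid = config$kappa_grid),
               error = function(err) NULL)
    })
    aniso <- classify_anisotropy(dir_fits, vgm, max_lag = attr(emp, "max_lag"))
  }

  val <- splits$validation
  y_val <- recode_response(val[[item]])
  p_val <- score_trend(model, val, fallback_reference = TRUE)
  kriged <- krige_field(val, resid_field, vgm, config$plan)
  records <- assemble_predictions(
    trend = data.frame(id = val$id, p = p_val),
    kriged = kriged,
    observed = data.frame(id = val$id, y = y_val),
    mode = config$backtransform)

  list(model = model, variogram = vgm, empirical = emp,
       directional = dir_fits, anisotropy = aniso,
       kriged = kriged, records = records,
       rmspe = rmspe(records),
       auc_large = roc_auc(y_val, p_val),
       auc_full = roc_auc(records))
}

variant_table_rows <- function(item, variant, v) {
  s <- v$variogram$structures
  fam <- vapply(s, `[[`, "", "family")
  t2 <- data.frame(
    item = item, detrending = variant,
    model = paste(fam, collapse = "-"),
    family1 = fam[1L],
    family2 = if (length(fam) > 1L) fam[2L] else NA_character_,
    nugget = v$variogram$nugget,
    psill1 = s[[1L]]$psill,
    psill2 = if (length(s) > 1L) s[[2L]]$psill else NA_real_,
    range1 = s[[1L]]$range,
    range2 = if (length(s) > 1L) s[[2L]]$range else NA_real_,
    rmspe = v$rmspe,
    rmspe_pct_change = NA_real_,
    anisotropy = v$anisotropy)
  t3 <- data.frame(
    item = item, detrending = variant,
    auc_large = v$auc_large, auc_full = v$auc_full,
    auc_pct_change_rater = NA_real_,
    auc_pct_change_scale = percent_change(v$auc_large, v$auc_full),
    accuracy = accuracy_label(v$auc_full))
  list(t2 = t2, t3 = t3)
}

#' Run the full spatial-prediction workflow for one item
#'
#' One shared train/validation split; then, for each detrending variant
#' (cubic spatial trend with and without rater adjustment): logistic trend
#' fit, deviance residuals, omnidirectional (and optionally 8 directional)
#' semivariograms, nested WLS model selection, local ordinary Kriging of
#' validation residuals, back-transformation and assembly, RMSPE/AUC and
#' percent-change evaluation.
#'
#' @param dataset an [audit_dataset()].
#' @param item item column name.
#' @param config a [run_config()].
#' @return list with `table2` / `table3` (two-row evaluation tables shaped
#'   like the packaged reference tables) and per-variant `artifacts`.
#' @export
run_item <- function(dataset, item, config = run_config()) {
  splits <- split_train_validation(dataset, item, config)
  variants <- list(spatial = FALSE, spatial_rater = TRUE)
  arts <- list()
  t2 <- t3 <- NULL
  for (vn in names(variants)) {
    v <- tryCatch(
      run_variant(splits, item, variants[[vn]], config),
      error = function(e) {
        stop(sprintf("item '%s', variant '%s': %s", item, vn,
                     conditionMessage(e)))
      })
    arts[[vn]] <- v
    rows <- variant_table_rows(item, vn, v)
    t2 <- rbind(t2, rows$t2)
    t3 <- rbind(t3, rows$t3)
  }
  ## paired percent changes (rater vs no rater)
  t2$rmspe_pct_change[2L] <- percent_change(t2$rmspe[1L], t2$rmspe[2L])
  t3$auc_pct_change_rater[2L] <- percent_change(t3$auc_full[1L],
                                                t3$auc_full[2L])
  list(item = item, table2 = t2, table3 = t3, artifacts = arts,
       n_train = nrow(splits$train), n_validation = nrow(splits$validation))
}

#' Run the workflow over many items and summarize
#'
#' Items that fail (e.g. single-class after the split) are recorded and
#' skipped; the summary counts are computed when every requested item
#' completed.
#'
#' @param dataset an [audit_dataset()].
#' @param items item column names; default all items in the dataset.
#' @param config a [run_config()].
#' @return list: `table2`, `table3` (stacked evaluation rows), `summary`
#'   (from [summarize_results_table()], or `NULL` on partial failure),
#'   `failures` (named error messages).
#' @export
run_all <- function(dataset, items = NULL, config = run_config()) {
  items <- items %||% attr(dataset, "items")
  t2 <- t3 <- NULL
  failures <- list()
  for (it in items) {
    res <- tryCatch(run_item(dataset, it, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[it]] <- conditionMessage(res)
      next
    }
    g <- attr(dataset, "item_groups")[[it]] %||% "synthetic"
    res$table2$group <- g
    res$table3$group <- g
    t2 <- rbind(t2, res$table2)
    t3 <- rbind(t3, res$table3)
  }
  summary <- NULL
  if (!length(failures) && !is.null(t2)) {
    summary <- tryCatch(summarize_results_table(t2, t3), error = function(e) NULL)
  }
  list(table2 = t2, table3 = t3, summary = summary, failures = failures)
}

#' Headline counts from the packaged reference tables
#'
#' Applies [summarize_results_table()] to the packaged 31-item evaluation
#' tables (report-only mode: no refitting).
#'
#' @param exclude_items optional items excluded from the group means.
#' @return the summary list.
#' @export
summarize_reference_tables <- function(exclude_items = character()) {
  summarize_results_table(load_reference_table(2), load_reference_table(3),
                          exclude_items = exclude_items)
}
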