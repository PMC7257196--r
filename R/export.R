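#' Export variogram bins and a fitted model
#'
#' Writes the empirical bins as CSV and the fitted nested model as JSON
#' (nugget, per-structure family / partial sill or *b* / range or *p* /
#' Matern smoothness, weighted SSE), mirroring the columns of the packaged
#' semivariogram reference table.
#'
#' @param emp an `empirical_variogram`.
#' @param model a `nested_variogram`.
#' @param bins_path,model_path output paths.
#' @return invisibly, both paths.
#' @export
write_variogram <- function(emp, model, bins_path, model_path) {
  utils::write.csv(as.data.frame(emp), bins_path, row.names = FALSE)
  obj <- list(
    nugget = model$nugget,
    structures = lapply(model$structures, function(s) {
      list(family = s$family, psill = s$psill, range = s$range,
           kappa = if (s$family == "matern") s$kappa else NULL)
    }),
    weighted_sse = model$sse,
    total_sill = total_sill(model),
    item = model$item,
    detrending = model$detrending)
  jsonlite::write_json(obj, model_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(bins_path, model_path))
}

#' Read a fitted nested model written by [write_variogram()]
#'
#' @param model_path JSON path.
#' @return a `nested_variogram`.
#' @export
read_variogram_model <- function(model_path) {
  obj <- jsonlite::read_json(model_path)
  structures <- lapply(obj$structures, function(s) {
    vgm_structure(s$family, psill = s$psill, range = s$range,
                  kappa = s$kappa %||% 0.5)
  })
  nested_variogram(obj$nugget, structures,
                   sse = obj$weighted_sse %||% NA_real_,
                   item = obj$item %||% NA_character_,
                   detrending = obj$detrending %||% NA_character_)
}

#' Export the per-item evaluation tables of a pipeline run
#'
#' Writes the semivariogram/RMSPE table, the AUC table, and (when present)
#' the summary counts, using exactly the column sets of the packaged
#' reference tables.
#'
#' @param result a [run_all()] result (or a [run_item()] result).
#' @param dir output directory, created if needed.
#' @return invisibly, the written paths.
#' @export
write_evaluation_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  t2 <- result$table2
  t3 <- result$table3
  p2 <- file.path(dir, "semivariograms.csv")
  p3 <- file.path(dir, "auc.csv")
  utils::write.csv(t2, p2, row.names = FALSE)
  utils::write.csv(t3, p3, row.names = FALSE)
  paths <- c(p2, p3)
  if (!is.null(result$summary)) {
    ps <- file.path(dir, "summary.json")
    jsonlite::write_json(result$summary, ps, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, ps)
  }
  invisible(paths)
}

#' Export kriged predictions as CSV
#'
#' @param kriged output of [krige_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kriged_csv <- function(kriged, path) {
  utils::write.csv(kriged, path, row.names = FALSE)
  invisible(path)
}
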