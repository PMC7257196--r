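#' Construct and validate an audit dataset
#'
#' An audit dataset holds one row per audited location: a unique `id`,
#' planar projected coordinates `x`/`y` in meters (the package never
#' reprojects; inputs are assumed to be in an equidistant projection so that
#' Euclidean distance is accurate), a `rater` factor, and one column per
#' audit item holding responses coded `1` = Yes, `2` = No, with `NA` allowed
#' for items that were not applicable at a location.
#'
#' @param df data.frame with columns `id`, `x`, `y`, `rater` and one or more
#'   `item_*` columns coded in `{1, 2, NA}`.
#' @return the validated data.frame with class `audit_dataset` and the item
#'   column names in `attr(, "items")`.
#' @export
audit_dataset <- function(df) {
  req <- c("id", "x", "y", "rater")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("audit dataset is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    dups <- unique(df$id[duplicated(df$id)])
    stop("duplicate location ids: ", paste(utils::head(dups, 5L), collapse = ", "))
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("coordinates must be finite")
  }
  items <- setdiff(names(df), req)
  for (it in items) {
    v <- df[[it]]
    bad <- which(!is.na(v) & !(v %in% c(1, 2)))
    if (length(bad)) {
      stop(sprintf("item '%s' has responses outside {1, 2, NA} at rows: %s",
                   it, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  df$rater <- factor(df$rater)
  class(df) <- c("audit_dataset", "data.frame")
  attr(df, "items") <- items
  df
}

#' @export
print.audit_dataset <- function(x, ...) {
  cat(sprintf("audit_dataset: %d locations, %d raters, %d items\n",
              nrow(x), nlevels(x$rater), length(attr(x, "items"))))
  cat("items:", paste(utils::head(attr(x, "items"), 8L), collapse = ", "),
      if (length(attr(x, "items")) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Read an audit point table from CSV
#'
#' Expects UTF-8, comma-separated, header row, with columns `id`, `x_m`,
#' `y_m` (or `x`, `y`), `rater`, and `item_*` columns coded 1 = Yes / 2 = No.
#'
#' @param path path to the CSV file.
#' @return an [audit_dataset()].
#' @export
read_audit_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("x_m" %in% names(df)) names(df)[names(df) == "x_m"] <- "x"
  if ("y_m" %in% names(df)) names(df)[names(df) == "y_m"] <- "y"
  audit_dataset(df)
}

#' Write an audit dataset to CSV
#'
#' @param dataset an [audit_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(dataset, path) {
  out <- as.data.frame(dataset)
  names(out)[names(out) == "x"] <- "x_m"
  names(out)[names(out) == "y"] <- "y_m"
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Recode audit responses to a 0/1 analysis vector
#'
#' The storage coding is 1 = Yes / 2 = No; models work on y with
#' 1 = Yes, 0 = No. Missing responses stay `NA` (dropped per item before
#' modeling, since item denominators differ).
#'
#' @param responses vector coded in `{1, 2, NA}`.
#' @return numeric vector in `{1, 0, NA}`.
#' @export
recode_response <- function(responses) {
  bad <- which(!is.na(responses) & !(responses %in% c(1, 2)))
  if (length(bad)) {
    stop("unknown response codes at positions: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ifelse(is.na(responses), NA_real_, ifelse(responses == 1, 1, 0))
}

#' Load a packaged reference summary table
#'
#' The package ships transcriptions of the three published summary tables of
#' the Essex County (NJ) 31-item drop-and-spin audit study: item prevalences
#' (table 1), fitted nested-semivariogram parameters with RMSPE (table 2),
#' and large-scale/full-model ROC AUC with percent changes (table 3). Tables
#' 2 and 3 carry two rows per item, one per detrending variant
#' (`spatial` = cubic spatial trend only, `spatial_rater` = trend + rater).
#'
#' @param table_id 1, 2 or 3.
#' @return a data.frame; tables 2 and 3 have 62 rows (31 items x 2 variants).
#' @export
load_reference_table <- function(table_id) {
  stopifnot(length(table_id) == 1L, table_id %in% 1:3)
  file <- switch(as.character(table_id),
    "1" = "table1_item_prevalence.csv",
    "2" = "table2_semivariograms.csv",
    "3" = "table3_auc.csv")
  path <- system.file("extdata", file, package = "auditkrige")
  if (!nzchar(path)) stop("packaged table not found: ", file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_expected <- if (table_id == 1) 31L else 62L
  if (nrow(df) != n_expected) {
    stop(sprintf("reference table %d is corrupt: %d rows, expected %d",
                 table_id, nrow(df), n_expected))
  }
  df
}

#' Write a block-group layer as GeoJSON plus covariate CSV
#'
#' Block-group units are axis-aligned rectangles (`xmin`, `xmax`, `ymin`,
#' `ymax` in meters); the GeoJSON encodes each as a Polygon feature and the
#' covariates go to a parallel CSV.
#'
#' @param layer a [block_group_layer()].
#' @param geojson_path output path for polygons.
#' @param csv_path output path for covariates.
#' @return invisibly, both paths.
#' @export
write_block_groups <- function(layer, geojson_path, csv_path) {
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    r <- layer[i, ]
    ring <- list(
      c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
      c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(
      type = "Feature",
      properties = list(unit = r$unit),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    geojson_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(layer), csv_path, row.names = FALSE)
  invisible(c(geojson_path, csv_path))
}

#' Read a rectangular-tile block-group layer written by [write_block_groups()]
#'
#' @param geojson_path polygons path.
#' @param csv_path covariates path.
#' @return a [block_group_layer()].
#' @export
read_block_groups <- function(geojson_path, csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  gj <- jsonlite::read_json(geojson_path)
  if (length(gj$features) != nrow(df)) {
    stop("GeoJSON and covariate CSV disagree on unit count")
  }
  block_group_layer(df)
}
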