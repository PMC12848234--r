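# Canonical schema for site-level gas-exchange tables. One row per
# measurement (or per site after aggregation); columns are the response,
# six climate covariates, ten edaphic covariates and two leaf traits.

.SCHEMA <- list(
  id       = c("site_id"),
  meta     = c("latitude", "longitude", "species"),
  response = c("vcmax_tmeas", "t_meas"),
  climate  = c("t_g", "vpd", "par", "ca", "elevation", "precipitation"),
  edaphic  = c("soil_ph", "soil_c", "soil_n", "soil_cn", "alpha_pt",
               "cec", "silt", "clay", "sand", "bulk_density"),
  traits   = c("lma", "na")
)

#' Canonical covariate names
#'
#' Column groups of the site-table schema: `"climate"` (growing-season
#' temperature, VPD, PAR, ambient CO2, elevation, precipitation), `"edaphic"`
#' (pH, soil C, soil N, C:N, Priestley-Taylor alpha, CEC, silt, clay, sand,
#' bulk density), `"traits"` (LMA and area-based leaf N) or `"all"`.
#'
#' @param group one of `"climate"`, `"edaphic"`, `"traits"`, `"all"`.
#' @return Character vector of canonical column names.
#' @export
site_covariates <- function(group = c("all", "climate", "edaphic", "traits")) {
  group <- match.arg(group)
  if (group == "all")
    c(.SCHEMA$climate, .SCHEMA$edaphic, .SCHEMA$traits)
  else .SCHEMA[[group]]
}

.all_columns <- function() unlist(.SCHEMA, use.names = FALSE)
.numeric_columns <- function() setdiff(.all_columns(), c("site_id", "species"))
.mandatory_columns <- function() c("site_id", "vcmax_tmeas", "t_meas")

.new_site_table <- function(df, level = "measurement", source = NA_character_) {
  rownames(df) <- NULL
  structure(df, class = c("site_table", "data.frame"),
            level = level, source = source)
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("Site table: %d rows, %d sites (%s level)\n",
              nrow(x), length(unique(x$site_id)), attr(x, "level")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

.validate_site_table <- function(df) {
  if (any(is.na(df$site_id) | df$site_id == ""))
    stop("site_id must be non-empty", call. = FALSE)
  bad <- which(!is.na(df$vcmax_tmeas) & df$vcmax_tmeas <= 0)
  if (length(bad))
    stop(sprintf("vcmax_tmeas must be positive (row %d)", bad[1]), call. = FALSE)
  if ("soil_ph" %in% names(df)) {
    ph <- df$soil_ph
    if (any(!is.na(ph) & (ph < 2 | ph > 11)))
      stop("soil_ph outside [2, 11]", call. = FALSE)
  }
  tex <- c("silt", "clay", "sand")
  if (all(tex %in% names(df))) {
    s <- rowSums(df[tex])
    if (any(!is.na(s) & (s < 95 | s > 105)))
      warning("silt+clay+sand outside [95, 105] for some rows", call. = FALSE)
  }
  invisible(df)
}

#' Read a site table from CSV
#'
#' Reads a measurement-level site table. Column names in the file are mapped
#' to the canonical schema either directly (when they already match) or via
#' `schema_config`, a named character vector or a key = value text file with
#' lines `file_column = canonical_name`. A `na_sentinel` key in the config
#' (e.g. `-9999`) declares an additional missing-value code; by default only
#' empty cells and `NA` are missing.
#'
#' @param path CSV file path.
#' @param schema_config optional mapping from file column names to canonical
#'   names: a named character vector (`c(myVcmax = "vcmax_tmeas")`) or the
#'   path of a key = value text file.
#' @return A `site_table` (data frame) at measurement level.
#' @export
read_site_table <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sentinel <- NULL
  map <- character(0)
  if (!is.null(schema_config)) {
    if (is.character(schema_config) && length(schema_config) == 1 &&
        is.null(names(schema_config)) && file.exists(schema_config)) {
      lines <- readLines(schema_config, warn = FALSE)
      lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
      kv <- strsplit(lines, "=", fixed = TRUE)
      keys <- trimws(vapply(kv, `[`, "", 1))
      vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
      map <- stats::setNames(vals, keys)
    } else map <- schema_config
    if ("na_sentinel" %in% names(map)) {
      sentinel <- map[["na_sentinel"]]
      map <- map[names(map) != "na_sentinel"]
    }
  }
  na_strings <- c("NA", "", if (!is.null(sentinel)) sentinel)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_strings,
                        check.names = FALSE)
  hit <- names(df) %in% names(map)
  names(df)[hit] <- unname(map[names(df)[hit]])
  unknown_unit <- grepl("\\(.*\\)", names(df))
  names(df) <- sub("\\s*\\(.*\\)$", "", names(df))  # strip unit annotations
  missing_mand <- setdiff(.mandatory_columns(), names(df))
  if (length(missing_mand))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  keep <- intersect(.all_columns(), names(df))
  df <- df[keep]
  for (col in setdiff(.all_columns(), names(df))) df[[col]] <- NA_real_
  df <- df[.all_columns()]
  df$site_id <- as.character(df$site_id)
  if ("species" %in% names(df)) df$species <- as.character(df$species)
  for (col in .numeric_columns()) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                     v[bad[1]], col, bad[1]), call. = FALSE)
      v <- vn
    }
    df[[col]] <- v
  }
  .validate_site_table(df)
  .new_site_table(df, level = "measurement", source = path)
}

#' Write a site table to CSV
#'
#' @param table a `site_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter to records with concurrent measurements
#'
#' Retains only measurement records with a recorded leaf measurement
#' temperature (and a positive Vcmax), and optionally only those with
#' concurrent leaf-trait (LMA and area-based leaf N) or complete edaphic
#' measurements. A count report is attached as attribute `"filter_report"`.
#'
#' @param table a measurement-level `site_table`.
#' @param require_traits require `lma` and `na` present.
#' @param require_edaphic require all ten edaphic covariates present.
#' @return The filtered `site_table`; issues a warning (not an error) when no
#'   records survive.
#' @export
filter_concurrent <- function(table, require_traits = FALSE,
                              require_edaphic = FALSE) {
  if (attr(table, "level") != "measurement")
    stop("filter_concurrent expects a measurement-level table", call. = FALSE)
  keep <- !is.na(table$t_meas) & !is.na(table$vcmax_tmeas)
  if (require_traits)
    keep <- keep & !is.na(table$lma) & !is.na(table$na)
  if (require_edaphic)
    keep <- keep & stats::complete.cases(as.data.frame(table)[.SCHEMA$edaphic])
  out <- table[keep, , drop = FALSE]
  out <- .new_site_table(as.data.frame(out), level = "measurement",
                         source = attr(table, "source"))
  attr(out, "filter_report") <- list(
    records_in = nrow(table), records_kept = nrow(out),
    sites_kept = length(unique(out$site_id)))
  if (nrow(out) == 0L)
    warning("no records survive the concurrent-measurement filter",
            call. = FALSE)
  out
}

#' Aggregate measurements to site means
#'
#' Collapses a measurement-level table to one row per site by unweighted
#' arithmetic means of each numeric column over non-missing values
#' (multi-species sites are pooled). Latitude/longitude are averaged as
#' metadata; species becomes the first observed label. Idempotent on
#' site-mean tables.
#'
#' @param table a `site_table`.
#' @return A site-mean `site_table`, one row per `site_id`, ordered by first
#'   appearance.
#' @export
aggregate_site_means <- function(table) {
  df <- as.data.frame(table)
  ids <- unique(df$site_id)
  num <- .numeric_columns()
  agg <- lapply(ids, function(id) {
    rows <- df[df$site_id == id, , drop = FALSE]
    out <- rows[1, , drop = FALSE]
    for (col in num) {
      v <- rows[[col]]
      out[[col]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, agg)
  .new_site_table(out, level = "site-mean", source = attr(table, "source"))
}
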