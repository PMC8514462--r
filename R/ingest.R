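#' Default FAOSTAT bulk-download column mapping
#'
#' Maps the logical fields the pipeline needs onto the column names of the
#' FAOSTAT bulk CSV dialect (`Area`, `Item`, `Element`, `Year`, `Value`).
#' Override any entry to ingest other dialects.
#'
#' @param country,item,element,year,value Column names in the source CSV.
#' @param element_keep Value of the element column identifying the harvested
#'   area rows; everything else is discarded.
#' @return Named list usable as `dialect_config` in [read_production_table()].
#' @export
faostat_dialect <- function(country = "Area", item = "Item",
                            element = "Element", year = "Year",
                            value = "Value",
                            element_keep = "Area harvested") {
  list(country = country, item = item, element = element,
       year = year, value = value, element_keep = element_keep)
}

#' Read a FAOSTAT-dialect area-harvested table
#'
#' Reads a long-format production CSV, keeps only rows whose element matches
#' the harvested-area element, and returns normalized records with columns
#' `country`, `year`, `crop_group`, `area_ha`. Rows with unparseable year or
#' value, or with negative area, are skipped; skip counts are attached as the
#' `"ingest_report"` attribute and reported via `message()`.
#'
#' @param path Path to the CSV file.
#' @param dialect_config Column mapping from [faostat_dialect()].
#' @param year_range Length-2 integer vector; records outside it are dropped
#'   (counted in the report). Default 1961-2017.
#' @return Data frame of records; attribute `ingest_report` holds counts of
#'   rows read, kept, element-filtered, and skipped by cause.
#' @export
read_production_table <- function(path, dialect_config = faostat_dialect(),
                                  year_range = c(1961L, 2017L)) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cfg <- dialect_config
  need <- unlist(cfg[c("country", "item", "element", "year", "value")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("configuration error: required column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  n_read <- nrow(raw)
  keep_el <- raw[[cfg$element]] == cfg$element_keep
  raw <- raw[!is.na(keep_el) & keep_el, , drop = FALSE]
  n_element_dropped <- n_read - nrow(raw)

  year <- suppressWarnings(as.integer(raw[[cfg$year]]))
  value <- suppressWarnings(as.numeric(raw[[cfg$value]]))
  bad_year <- is.na(year)
  bad_value <- is.na(value) | (!is.na(value) & value < 0)
  ok <- !bad_year & !bad_value
  out <- data.frame(
    country = as.character(raw[[cfg$country]])[ok],
    year = year[ok],
    crop_group = as.character(raw[[cfg$item]])[ok],
    area_ha = value[ok],
    stringsAsFactors = FALSE
  )
  in_range <- out$year >= year_range[1L] & out$year <= year_range[2L]
  n_out_of_range <- sum(!in_range)
  out <- out[in_range, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("empty input: no 'Area harvested' records remain after parsing ", path)
  }
  report <- list(
    rows_read = n_read,
    rows_kept = nrow(out),
    element_filtered = n_element_dropped,
    skipped_bad_year = sum(bad_year & !is.na(raw[[cfg$year]]) | bad_year),
    skipped_bad_value = sum(bad_value[!bad_year]),
    out_of_range = n_out_of_range
  )
  message(sprintf("ingest: %d rows read, %d kept (%d wrong element, %d skipped, %d out of range)",
                  report$rows_read, report$rows_kept, report$element_filtered,
                  report$skipped_bad_year + report$skipped_bad_value,
                  report$out_of_range))
  rownames(out) <- NULL
  attr(out, "ingest_report") <- report
  out
}

# FAO item-label harmonization rules. "Cottonlint" and "Cottonseed" are the
# fibre and seed fractions of one crop and are compiled as "Seedcotton";
# "Palmkernels" is the seed fraction of oil palm fruit; the removed labels are
# either unlinked to a species, non-plant, or a by-product.
.merge_into_seedcotton <- c("Cottonlint", "Cottonseed")
.rename_map <- c(Palmkernels = "Oilpalmfruit")
.removed_labels <- c("Fruitpomenes", "Fruitstonenes", "Grainmixed",
                     "Mushroomsandtruffles", "Coir")

#' Harmonize FAO crop-group labels
#'
#' Applies the fixed label-harmonization rules: merges `Cottonlint` and
#' `Cottonseed` into `Seedcotton` (areas summed within country-year, so
#' harvested area is conserved), renames `Palmkernels` to `Oilpalmfruit`,
#' and removes `Fruitpomenes`, `Fruitstonenes`, `Grainmixed`,
#' `Mushroomsandtruffles` and `Coir`. After harmonization, duplicate
#' (country, year, crop_group) rows are summed so keys are unique.
#'
#' @param records Normalized record data frame (see [read_production_table()]).
#' @return Harmonized records; attribute `harmonization_report` carries counts
#'   of merged, renamed and removed rows.
#' @export
harmonize_crop_groups <- function(records) {
  check_records(records)
  lab <- records$crop_group
  n_removed <- sum(lab %in% .removed_labels)
  n_merged <- sum(lab %in% .merge_into_seedcotton)
  n_renamed <- sum(lab %in% names(.rename_map))

  records <- records[!(lab %in% .removed_labels), , drop = FALSE]
  lab <- records$crop_group
  lab[lab %in% .merge_into_seedcotton] <- "Seedcotton"
  ren <- lab %in% names(.rename_map)
  lab[ren] <- unname(.rename_map[lab[ren]])
  records$crop_group <- lab

  # collapse duplicates (merge semantics: areas summed per country-year-group)
  key <- paste(records$country, records$year, records$crop_group, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(records$area_ha, group = key, reorder = FALSE)
    first <- !duplicated(key)
    records <- records[first, , drop = FALSE]
    records$area_ha <- agg[match(key[first], rownames(agg)), 1L]
  }
  rownames(records) <- NULL
  attr(records, "harmonization_report") <- list(
    merged_rows = n_merged, renamed_rows = n_renamed, removed_rows = n_removed,
    distinct_groups = length(unique(records$crop_group))
  )
  records
}

#' Filter records to a configured country set
#'
#' Drops records whose country is not in `valid_countries` — used to exclude
#' dissolved states (e.g. Yugoslavia) so the analysis covers only currently
#' recognized countries. An optional alias table renames country keys first
#' (FAO names drift across data snapshots).
#'
#' @param records Normalized record data frame.
#' @param valid_countries Character vector of retained country keys.
#' @param aliases Optional named character vector mapping source names to
#'   canonical names, applied before filtering.
#' @return Filtered records; attribute `country_report` lists retained and
#'   dropped countries.
#' @export
filter_countries <- function(records, valid_countries, aliases = NULL) {
  check_records(records)
  if (length(valid_countries) == 0L) {
    stop("configuration error: `valid_countries` is empty")
  }
  if (!is.null(aliases)) {
    hit <- records$country %in% names(aliases)
    records$country[hit] <- unname(aliases[records$country[hit]])
  }
  keep <- records$country %in% valid_countries
  dropped <- sort(unique(records$country[!keep]))
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "country_report") <- list(
    retained = sort(unique(records$country)),
    dropped = dropped
  )
  records
}

#' Write normalized records to CSV
#'
#' @param records Record data frame.
#' @param path Output path; header is `country,year,crop_group,area_ha`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  check_records(records)
  utils::write.csv(records[, c("country", "year", "crop_group", "area_ha")],
                   path, row.names = FALSE)
  invisible(path)
}
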