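#' Crop-group richness of one country-year
#'
#' Richness `S` is the number of crop groups with strictly positive harvested
#' area. Zero-area entries are treated as absences, not as zero-abundance
#' presences, so they never inflate `S`.
#'
#' @param areas Named (or unnamed) numeric vector of harvested areas in
#'   hectares, one entry per crop group.
#' @return Integer count of crop groups with `area > 0`.
#' @examples
#' richness(c(wheat = 5, maize = 0.1)) # 2
#' richness(c(wheat = 5, maize = 0))   # 1
#' @export
richness <- function(areas) {
  areas <- check_areas(areas)
  s <- sum(areas > 0)
  if (s == 0L) {
    stop("no crop group with positive area: country-year has no cultivation record")
  }
  as.integer(s)
}

#' Shannon-Weiner diversity of one country-year
#'
#' Computes `H' = -sum(p_i * log(p_i))` in nats, where `p_i` is the share of
#' total harvested area held by crop group `i`. Zero-area groups are dropped
#' before forming proportions.
#'
#' @inheritParams richness
#' @return Shannon index in nats (`>= 0`); 0 exactly when a single group is
#'   present.
#' @examples
#' shannon(c(5, 5))        # log(2)
#' shannon(c(7, 2, 1) * 3) # scale-invariant
#' @export
shannon <- function(areas) {
  areas <- check_areas(areas)
  areas <- areas[areas > 0]
  if (length(areas) == 0L) {
    stop("no crop group with positive area: country-year has no cultivation record")
  }
  p <- areas / sum(areas)
  -sum(p * log(p))
}

#' Pielou evenness of one country-year
#'
#' `J' = H' / ln(S)`, in `[0, 1]`, with 1 meaning perfectly equal area shares.
#' When `S = 1` the denominator is zero and evenness is undefined; `NA` is
#' returned and such country-years are excluded from downstream evenness
#' modelling.
#'
#' @inheritParams richness
#' @return Evenness in `[0, 1]`, or `NA_real_` when only one group is present.
#' @export
pielou <- function(areas) {
  s <- richness(areas)
  if (s == 1L) {
    return(NA_real_)
  }
  shannon(areas) / log(s)
}

check_areas <- function(areas) {
  if (!is.numeric(areas) || length(areas) == 0L) {
    stop("`areas` must be a non-empty numeric vector")
  }
  if (anyNA(areas)) {
    stop("`areas` contains missing values")
  }
  if (any(areas < 0)) {
    stop("negative harvested area is invalid")
  }
  areas
}

#' Per-country-per-year diversity table
#'
#' Collapses harmonized long-format crop records into one row per
#' (country, year) carrying richness `S`, Shannon `H`, Pielou `J` and the
#' summed harvested area. Country-years whose records are all zero-area are
#' dropped (no cultivation). `J` is `NA` where `S = 1`; the logical column
#' `J_defined` flags usable evenness values.
#'
#' @param records Data frame with columns `country`, `year`, `crop_group`,
#'   `area_ha` (the normalized record layout produced by
#'   [read_production_table()] / [harmonize_crop_groups()]).
#' @return Data frame with columns `country`, `year`, `S`, `H`, `J`,
#'   `J_defined`, `total_area`, ordered by country then year.
#' @export
diversity_table <- function(records) {
  check_records(records)
  records <- records[records$area_ha > 0, , drop = FALSE]
  if (nrow(records) == 0L) {
    return(data.frame(
      country = character(), year = integer(), S = integer(),
      H = numeric(), J = numeric(), J_defined = logical(),
      total_area = numeric(), stringsAsFactors = FALSE
    ))
  }
  key <- interaction(records$country, records$year, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    a <- d$area_ha
    s <- length(a)
    h <- shannon(a)
    data.frame(
      country = d$country[1L], year = d$year[1L],
      S = as.integer(s), H = h,
      J = if (s > 1L) h / log(s) else NA_real_,
      J_defined = s > 1L,
      total_area = sum(a),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$country, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_records <- function(records) {
  need <- c("country", "year", "crop_group", "area_ha")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  invisible(records)
}
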