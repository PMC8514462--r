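#' Configuration for the synthetic FAOSTAT-like generator
#'
#' Describes a world with known ground truth for every pipeline stage:
#' per-country richness follows a two-breakpoint piecewise-linear trajectory
#' (crops are actually introduced/retired so presence counts, not just
#' latent means, follow it); harvested areas follow a ranked geometric
#' abundance series whose decay parameter sets the evenness trajectory;
#' countries carry latitude, HDI and a nested continent/region structure
#' that can shift the onset year.
#'
#' @param n_countries Number of countries.
#' @param years Integer vector of years (default 1961:2017).
#' @param S0 Baseline richness in the first year.
#' @param psi1,psi2 True breakpoint years (must satisfy
#'   `min(years) < psi1 < psi2 < max(years)`).
#' @param slopes Length-3 vector of segment slopes (before `psi1`, between,
#'   after `psi2`) in crop groups per year.
#' @param richness_sd Gaussian noise sd on the latent richness scale.
#' @param theta_start,theta_end Geometric rank-abundance decay parameter at
#'   the first and last year (linearly interpolated between); `theta = 1`
#'   gives equal areas and evenness exactly 1, smaller values concentrate
#'   area in dominant crops.
#' @param pool_size Size of the global crop-group pool.
#' @param total_area Median country agricultural area (ha); per-country
#'   totals are drawn log-normally around it and held constant over years.
#' @param n_continents,regions_per_continent Nested spatial structure.
#' @param sd_continent,sd_region,sd_resid Standard deviations (years) of the
#'   continent, region-within-continent and residual shifts applied to each
#'   country's onset `psi1`.
#' @param hdi_range HDI values are drawn uniformly from this interval.
#' @param hdi_onset_slope Linear effect (years per HDI unit) of centred HDI
#'   on the onset.
#' @param gradient Optional latitude gradient: list with `beta0`, `beta1`,
#'   `beta2`, `sd`; when supplied, each country's `S0` is set from its
#'   absolute latitude via the quadratic.
#' @param lat_range Latitudes are drawn uniformly from this interval
#'   (degrees absolute).
#' @param seed Mandatory integer seed; all generator randomness flows from
#'   it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 30L, years = 1961:2017,
                             S0 = 20L, psi1 = 1980, psi2 = 1995,
                             slopes = c(0, 1, 0), richness_sd = 0,
                             theta_start = 0.85, theta_end = 0.85,
                             pool_size = 120L, total_area = 1e6,
                             n_continents = 4L, regions_per_continent = 3L,
                             sd_continent = 0, sd_region = 0, sd_resid = 0,
                             hdi_range = c(0.35, 0.95), hdi_onset_slope = 0,
                             gradient = NULL, lat_range = c(0, 70),
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory for the synthetic generator")
  stopifnot(length(slopes) == 3L, length(years) >= 7L)
  if (!(min(years) < psi1 && psi1 < psi2 && psi2 < max(years))) {
    stop("config error: breakpoints must satisfy min(years) < psi1 < psi2 < max(years)")
  }
  if (S0 < 1) stop("config error: S0 must be >= 1")
  if (any(c(richness_sd, sd_continent, sd_region, sd_resid) < 0)) {
    stop("config error: standard deviations must be non-negative")
  }
  if (theta_start <= 0 || theta_start > 1 || theta_end <= 0 || theta_end > 1) {
    stop("config error: theta must lie in (0, 1]")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Piecewise-linear mean richness, parameterized by segment slopes.
piecewise_mean <- function(years, S0, psi1, psi2, slopes) {
  b <- slopes[1L]
  cc <- slopes[2L] - slopes[1L]
  d <- slopes[3L] - slopes[2L]
  t0 <- min(years)
  S0 + b * (years - t0) + cc * pmax(years - psi1, 0) + d * pmax(years - psi2, 0)
}

#' Evenness of a geometric rank-abundance series
#'
#' Closed-form Pielou evenness of `S` groups with abundances proportional to
#' `theta^(rank - 1)`: the truth against which realized evenness is checked.
#'
#' @param S Number of groups.
#' @param theta Decay parameter in `(0, 1]`.
#' @return Evenness in `(0, 1]`; 1 when `theta = 1` or `S = 1` is `NA`.
#' @export
geometric_evenness <- function(S, theta) {
  if (S < 2L) return(NA_real_)
  if (theta == 1) return(1)
  w <- theta^(seq_len(S) - 1L)
  p <- w / sum(w)
  -sum(p * log(p)) / log(S)
}

#' Generate one country's crop records
#'
#' Realizes the piecewise richness trajectory (rounded, floored at 1,
#' Gaussian noise on the latent scale) by introducing/retiring crops from
#' the country's ordered pool, and assigns areas from the geometric
#' rank-abundance series scaled to the country's total area.
#'
#' @param country Country label.
#' @param years Integer years.
#' @param S0,psi1,psi2,slopes,richness_sd Trajectory truth (see
#'   [synthetic_config()]).
#' @param theta Decay parameter per year (length 1 or `length(years)`).
#' @param pool Character vector of crop-group names (the country's own
#'   preference order; the first `S_t` entries are cultivated in year `t`).
#' @param total_area Country agricultural area in ha (constant over years).
#' @param seed Integer seed (bit-identical regeneration for equal seeds).
#' @return Data frame of records `country,year,crop_group,area_ha` plus a
#'   `truth` attribute with the realized `S` per year.
#' @export
generate_country_series <- function(country, years, S0, psi1, psi2, slopes,
                                    richness_sd = 0, theta = 0.85,
                                    pool, total_area = 1e6, seed) {
  if (!(min(years) < psi1 && psi1 < psi2 && psi2 < max(years))) {
    stop("config error: breakpoints outside the year range")
  }
  set.seed(seed)
  theta <- rep_len(theta, length(years))
  mu <- piecewise_mean(years, S0, psi1, psi2, slopes)
  s_real <- round(mu + stats::rnorm(length(years), 0, richness_sd))
  s_real <- pmin(pmax(s_real, 1L), length(pool))
  rows <- lapply(seq_along(years), function(i) {
    s <- s_real[i]
    w <- theta[i]^(seq_len(s) - 1L)
    data.frame(country = country, year = years[i],
               crop_group = pool[seq_len(s)],
               area_ha = total_area * w / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(year = years, S = as.integer(s_real),
                                   theta = theta)
  out
}

#' Generate a full synthetic dataset with truth tables
#'
#' Draws country metadata (continent/region tree, HDI, latitude), builds
#' each country's true trajectory (onset shifted by the nested spatial
#' effects and the HDI slope; `S0` set from the latitude gradient when one
#' is configured), and emits crop records, metadata, and truth tables
#' aligned with every downstream estimate.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (long-format crop records), `meta` (columns
#'   `country`, `latitude_abs`, `continent`, `region`, `hdi`,
#'   `total_area`), and `truth` (per-country `psi1`, `psi2`, slopes, `S0`,
#'   onset/duration/rate, evenness schedule endpoints).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_countries
  countries <- sprintf("Country_%03d", seq_len(n))
  if (anyDuplicated(countries)) stop("config error: duplicate country names")
  pool_names <- sprintf("crop_%03d", seq_len(cfg$pool_size))

  continent <- sprintf("Continent_%d",
                       rep_len(seq_len(cfg$n_continents), n))
  region_idx <- rep_len(seq_len(cfg$n_continents * cfg$regions_per_continent), n)
  region <- sprintf("Region_%d", region_idx)
  hdi <- stats::runif(n, cfg$hdi_range[1L], cfg$hdi_range[2L])
  lat <- stats::runif(n, cfg$lat_range[1L], cfg$lat_range[2L])
  total_area <- cfg$total_area * stats::rlnorm(n, 0, 0.5)

  cont_eff <- stats::rnorm(cfg$n_continents, 0, cfg$sd_continent)
  reg_eff <- stats::rnorm(cfg$n_continents * cfg$regions_per_continent,
                          0, cfg$sd_region)
  onset_shift <- cont_eff[rep_len(seq_len(cfg$n_continents), n)] +
    reg_eff[region_idx] +
    cfg$hdi_onset_slope * (hdi - mean(hdi)) +
    stats::rnorm(n, 0, cfg$sd_resid)
  yr <- range(cfg$years)
  psi1_c <- pmin(pmax(cfg$psi1 + onset_shift, yr[1L] + 2), cfg$psi2 - 1)

  S0_c <- if (!is.null(cfg$gradient)) {
    g <- cfg$gradient
    pmax(round(g$beta0 + g$beta1 * lat + g$beta2 * lat^2 +
                 stats::rnorm(n, 0, g$sd)), 2L)
  } else {
    rep(cfg$S0, n)
  }

  theta_path <- cfg$theta_start +
    (cfg$theta_end - cfg$theta_start) *
    (cfg$years - yr[1L]) / (yr[2L] - yr[1L])

  country_seeds <- cfg$seed + seq_len(n)
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    # per-country crop preference order, drawn from the shared pool
    ord <- sample(pool_names)
    rec_list[[i]] <- generate_country_series(
      countries[i], cfg$years, S0_c[i], psi1_c[i], cfg$psi2, cfg$slopes,
      richness_sd = cfg$richness_sd, theta = theta_path, pool = ord,
      total_area = total_area[i], seed = country_seeds[i]
    )
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  meta <- data.frame(
    country = countries, latitude_abs = lat, continent = continent,
    region = region, hdi = hdi, total_area = total_area,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    country = countries, S0 = S0_c, psi1 = psi1_c, psi2 = cfg$psi2,
    slope1 = cfg$slopes[1L], slope2 = cfg$slopes[2L], slope3 = cfg$slopes[3L],
    onset = psi1_c, duration = cfg$psi2 - psi1_c, rate = cfg$slopes[2L],
    theta_start = cfg$theta_start, theta_end = cfg$theta_end,
    stringsAsFactors = FALSE
  )
  list(records = records, meta = meta, truth = truth, config = cfg)
}

#' Write records as a FAOSTAT-dialect CSV
#'
#' Emits the bulk-download layout (`Area,Item,Element,Year,Unit,Value`) that
#' [read_production_table()] ingests, enabling round-trip tests.
#'
#' @param records Normalized record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faostat_csv <- function(records, path) {
  check_records(records)
  utils::write.csv(data.frame(
    Area = records$country, Item = records$crop_group,
    Element = "Area harvested", Year = records$year, Unit = "ha",
    Value = records$area_ha, stringsAsFactors = FALSE
  ), path, row.names = FALSE)
  invisible(path)
}

#' Simulate a nested indicator design for mixed-model checks
#'
#' Direct simulation of the variance-component world: one indicator value
#' per country with continent, region-within-continent and residual
#' Gaussian components plus an HDI fixed effect.
#'
#' @param n_continents,regions_per_continent,countries_per_region Design.
#' @param sd_continent,sd_region,sd_resid Component standard deviations.
#' @param intercept,hdi_slope Fixed effects; HDI drawn uniform on
#'   `hdi_range`.
#' @param hdi_range HDI sampling interval.
#' @param seed Integer seed.
#' @return Data frame `country`, `continent`, `region`, `hdi`, `value`.
#' @export
simulate_nested_design <- function(n_continents = 6L,
                                   regions_per_continent = 3L,
                                   countries_per_region = 10L,
                                   sd_continent = 2, sd_region = 1,
                                   sd_resid = 1, intercept = 0,
                                   hdi_slope = 0, hdi_range = c(0.35, 0.95),
                                   seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  grid <- expand.grid(
    region_in_cont = seq_len(regions_per_continent),
    continent_i = seq_len(n_continents),
    rep = seq_len(countries_per_region)
  )
  n <- nrow(grid)
  cont_eff <- stats::rnorm(n_continents, 0, sd_continent)
  reg_eff <- stats::rnorm(n_continents * regions_per_continent, 0, sd_region)
  reg_id <- (grid$continent_i - 1L) * regions_per_continent +
    grid$region_in_cont
  hdi <- stats::runif(n, hdi_range[1L], hdi_range[2L])
  value <- intercept + hdi_slope * hdi + cont_eff[grid$continent_i] +
    reg_eff[reg_id] + stats::rnorm(n, 0, sd_resid)
  data.frame(
    country = sprintf("Country_%04d", seq_len(n)),
    continent = sprintf("Continent_%d", grid$continent_i),
    region = sprintf("Region_%d", reg_id),
    hdi = hdi, value = value, stringsAsFactors = FALSE
  )
}

#' Simulate a quadratic latitude-richness sample
#'
#' One richness value per country from
#' `S = beta0 + beta1 * L + beta2 * L^2 + N(0, sd)` with latitudes uniform
#' on `lat_range` — the stated world for gradient-recovery checks.
#'
#' @param n Number of countries.
#' @param beta Length-3 coefficient vector (default `c(20, 1.5, -0.02)`,
#'   peaking at 37.5 degrees).
#' @param sd Noise standard deviation.
#' @param lat_range Latitude sampling interval (degrees absolute).
#' @param seed Integer seed.
#' @return Data frame `latitude`, `S`.
#' @export
simulate_latitude_gradient <- function(n = 160L, beta = c(20, 1.5, -0.02),
                                       sd = 2, lat_range = c(0, 70), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  lat <- stats::runif(n, lat_range[1L], lat_range[2L])
  S <- beta[1L] + beta[2L] * lat + beta[3L] * lat^2 + stats::rnorm(n, 0, sd)
  data.frame(latitude = lat, S = S)
}
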