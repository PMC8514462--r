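#' Build a pipeline run configuration
#'
#' Exactly one of `production_csv` (real FAOSTAT-dialect input, with
#' `meta_csv` for country metadata) or `synthetic` (a [synthetic_config()])
#' must be supplied.
#'
#' @param production_csv Path to a FAOSTAT-dialect CSV, or `NULL`.
#' @param meta_csv Path to country metadata CSV (columns `country`,
#'   `latitude_abs`, `continent`, `region`, `hdi`, optionally
#'   `total_area`), or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param year_range Length-2 analysis year range.
#' @param valid_countries Optional country whitelist for [filter_countries()]
#'   (`NULL` keeps all).
#' @param init_psi1,init_psi2 Breakpoint initials for the segmented fits.
#' @param overrides Named list of per-country breakpoint initials.
#' @param n_perm PERMANOVA permutation count.
#' @param nmds_starts NMDS start count.
#' @param composition_year_step Use every k-th year when building the
#'   composition matrix (1 = all years); controls the cost of the
#'   distance-matrix stages.
#' @param seed Seed recorded in the manifest and used by all stochastic
#'   stages.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(production_csv = NULL, meta_csv = NULL,
                            synthetic = NULL, year_range = c(1961L, 2017L),
                            valid_countries = NULL,
                            init_psi1 = 1975, init_psi2 = 2000,
                            overrides = NULL, n_perm = 99L,
                            nmds_starts = 4L, composition_year_step = 1L,
                            seed = 1L) {
  has_real <- !is.null(production_csv)
  has_syn <- !is.null(synthetic)
  if (has_real == has_syn) {
    stop("exactly one of `production_csv` or `synthetic` must be supplied")
  }
  if (has_syn) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(as.list(environment())[c(
    "production_csv", "meta_csv", "synthetic", "year_range",
    "valid_countries", "init_psi1", "init_psi2", "overrides", "n_perm",
    "nmds_starts", "composition_year_step", "seed"
  )], class = "run_config")
}

write_stage <- function(df, outdir, name, counts) {
  utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                   row.names = FALSE, na = "")
  counts[[name]] <- nrow(df)
  counts
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or synthetic generation), diversity metrics,
#' per-country segmented fits for richness and evenness, change indicators
#' and their summaries, composition analysis (Bray-Curtis, NMDS,
#' permutational MANOVA, per-year dispersion), latitudinal gradients, area
#' diagnostics and the HDI mixed models. Every stage writes a CSV into
#' `outdir`; `manifest.json` records the config hash, seed, per-stage row
#' counts and the non-converged-country list. A stage failure aborts with
#' the stage name, retaining partial outputs and an `incomplete` manifest.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list of all stage results plus the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  manifest_path <- file.path(outdir, "manifest.json")
  config_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(config_path))

  stage <- "ingest"
  result <- tryCatch({
    if (!is.null(config$synthetic)) {
      message("stage ingest: generating synthetic dataset (seed ",
              config$synthetic$seed, ")")
      sim <- generate_dataset(config$synthetic)
      records <- sim$records
      meta <- sim$meta
      counts <- write_stage(sim$truth, outdir, "truth", counts)
    } else {
      message("stage ingest: reading ", config$production_csv)
      records <- read_production_table(config$production_csv,
                                       year_range = config$year_range)
      records <- harmonize_crop_groups(records)
      if (!is.null(config$valid_countries)) {
        records <- filter_countries(records, config$valid_countries)
      }
      meta <- if (!is.null(config$meta_csv)) {
        utils::read.csv(config$meta_csv, stringsAsFactors = FALSE)
      } else NULL
    }
    counts <- write_stage(records, outdir, "records", counts)

    stage <- "diversity"
    div <- diversity_table(records)
    counts <- write_stage(div, outdir, "diversity", counts)

    stage <- "segmented"
    fits_S <- fit_country_trends(div, "S", config$init_psi1,
                                 config$init_psi2, config$overrides)
    fits_J <- fit_country_trends(div, "J", config$init_psi1,
                                 config$init_psi2, config$overrides)
    fits <- rbind(fits_S, fits_J)
    counts <- write_stage(fits, outdir, "segmented_fits", counts)
    nonconv <- fits$country[!fits$converged]

    stage <- "indicators"
    ind <- rbind(indicator_table(fits_S), indicator_table(fits_J))
    counts <- write_stage(ind, outdir, "indicators", counts)
    summ <- do.call(rbind, lapply(split(ind, ind$metric),
                                  summarize_indicators))
    rownames(summ) <- NULL
    counts <- write_stage(summ, outdir, "indicator_summaries", counts)

    stage <- "composition"
    comp_rec <- records[records$year %in%
      seq(config$year_range[1L], config$year_range[2L],
          by = config$composition_year_step), , drop = FALSE]
    cm <- community_matrix(comp_rec)
    d <- bray_curtis_matrix(cm)
    ord <- nmds_ordination(d, k = 2L, n_starts = config$nmds_starts,
                           seed = config$seed)
    nmds_df <- data.frame(sample = rownames(ord$points),
                          axis1 = ord$points[, 1L], axis2 = ord$points[, 2L],
                          stress = ord$stress, stringsAsFactors = FALSE)
    counts <- write_stage(nmds_df, outdir, "nmds", counts)
    pmv <- permanova(
      d, data.frame(year = attr(cm, "year"),
                    country = factor(attr(cm, "country"))),
      n_perm = config$n_perm, seed = config$seed)
    counts <- write_stage(as.data.frame(pmv), outdir, "permanova", counts)
    disp <- year_dispersion(d, attr(cm, "year"))
    counts <- write_stage(disp, outdir, "year_dispersion", counts)

    stage <- "gradients"
    grad_df <- area_df <- NULL
    if (!is.null(meta) && "latitude_abs" %in% names(meta)) {
      yrs <- range(div$year)
      both <- intersect(div$country[div$year == yrs[1L]],
                        div$country[div$year == yrs[2L]])
      grad_rows <- lapply(yrs, function(yy) {
        dd <- div[div$year == yy & div$country %in% both, , drop = FALSE]
        lat <- meta$latitude_abs[match(dd$country, meta$country)]
        g <- fit_latitude_gradient(lat, dd$S, year = yy)
        data.frame(year = yy, beta0 = g$beta0, se0 = g$se0, beta1 = g$beta1,
                   se1 = g$se1, beta2 = g$beta2, se2 = g$se2, r2 = g$r2,
                   p = g$p, peak_latitude = g$peak_latitude, n = g$n)
      })
      grad_df <- do.call(rbind, grad_rows)
      counts <- write_stage(grad_df, outdir, "latitude_gradients", counts)
      if ("total_area" %in% names(meta)) {
        areas <- stats::setNames(meta$total_area, meta$country)
        area_df <- do.call(rbind, lapply(split(ind, ind$metric), function(x)
          cbind(metric = x$metric[1L], area_regression(x, areas))))
        rownames(area_df) <- NULL
        counts <- write_stage(area_df, outdir, "area_regressions", counts)
      }
    }

    stage <- "socio"
    socio_df <- NULL
    if (!is.null(meta) && all(c("hdi", "continent", "region") %in%
                              names(meta))) {
      socio_df <- fit_socio_models(ind, meta)
      counts <- write_stage(socio_df, outdir, "socio_models", counts)
    }

    manifest <- list(
      config_hash = cfg_hash, seed = config$seed, incomplete = FALSE,
      stage_rows = counts, non_converged_countries = unique(nonconv)
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(records = records, meta = meta, diversity = div,
                   fits = fits, indicators = ind, summaries = summ,
                   nmds = ord, permanova = pmv, dispersion = disp,
                   gradients = grad_df, area_regressions = area_df,
                   socio = socio_df, manifest = manifest))
  }, error = function(e) {
    manifest <- list(config_hash = cfg_hash, seed = config$seed,
                     incomplete = TRUE, failed_stage = stage,
                     error = conditionMessage(e), stage_rows = counts)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

parse_cli_flags <- function(args) {
  flags <- list()
  positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      flags[[gsub("-", "_", key)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn <- do.call(synthetic_config, raw$synthetic)
  }
  args <- raw[setdiff(names(raw), "synthetic")]
  do.call(pipeline_config, c(args, list(synthetic = syn)))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (generate a synthetic FAOSTAT-dialect dataset),
#' `run` (full pipeline), `fit-country` (one country's segmented fit from a
#' diversity CSV), `permanova` (composition test from a records CSV),
#' `report` (print a run manifest). Shared flags: `--config` (JSON run
#' config), `--seed`, `--outdir`, `--n-perm`, `--nmds-starts`. An
#' executable wrapper is installed at `exec/cropdiv`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly on success.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: cropdiv <simulate|run|fit-country|permanova|report> [--config F] [--seed N] [--outdir D] [--n-perm N] [--nmds-starts N]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  parsed <- parse_cli_flags(args[-1L])
  fl <- parsed$flags
  outdir <- fl$outdir %||% "cropdiv_out"
  seed <- as.integer(fl$seed %||% "1")

  if (cmd == "simulate") {
    cfg <- if (!is.null(fl$config)) {
      do.call(synthetic_config,
              jsonlite::read_json(fl$config, simplifyVector = TRUE))
    } else synthetic_config(seed = seed)
    sim <- generate_dataset(cfg)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_faostat_csv(sim$records, file.path(outdir, "production.csv"))
    utils::write.csv(sim$meta, file.path(outdir, "country_meta.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)
    message("simulate: wrote production.csv, country_meta.csv, truth.csv to ",
            outdir)
  } else if (cmd == "run") {
    cfg <- if (!is.null(fl$config)) config_from_json(fl$config) else
      stop("run requires --config")
    if (!is.null(fl$n_perm)) cfg$n_perm <- as.integer(fl$n_perm)
    if (!is.null(fl$nmds_starts)) cfg$nmds_starts <- as.integer(fl$nmds_starts)
    if (!is.null(fl$seed)) cfg$seed <- seed
    run_pipeline(cfg, outdir)
    message("run: pipeline complete, outputs in ", outdir)
  } else if (cmd == "fit-country") {
    div <- utils::read.csv(fl$input, stringsAsFactors = FALSE)
    d <- div[div$country == fl$country, , drop = FALSE]
    if (nrow(d) == 0L) stop("country not found: ", fl$country)
    resp <- fl$response %||% "S"
    print(fit_segmented(d$year, d[[resp]], response_label = resp))
  } else if (cmd == "permanova") {
    records <- utils::read.csv(fl$input, stringsAsFactors = FALSE)
    cm <- community_matrix(records)
    d <- bray_curtis_matrix(cm)
    print(permanova(
      d, data.frame(year = attr(cm, "year"),
                    country = factor(attr(cm, "country"))),
      n_perm = as.integer(fl$n_perm %||% "99"), seed = seed))
  } else if (cmd == "report") {
    m <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
    cat("run manifest (config", m$config_hash, ")\n")
    cat("  seed:", m$seed, " incomplete:", m$incomplete, "\n")
    for (nm in names(m$stage_rows)) {
      cat(sprintf("  %-20s %d rows\n", nm, m$stage_rows[[nm]]))
    }
    if (length(m$non_converged_countries) > 0L) {
      cat("  non-converged:",
          paste(m$non_converged_countries, collapse = ", "), "\n")
    }
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
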