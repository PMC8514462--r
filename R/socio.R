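#' Distribution-based indicator transform
#'
#' Chooses identity versus log transform for a vector of indicator values by
#' the same normal-vs-log-normal AIC rule as [summarize_indicator()]. When
#' any value is non-positive the log candidate uses a configured positive
#' offset (e.g. `log(x + 10)` for rate indicators spanning negatives); the
#' label records exactly what was applied.
#'
#' @param values Numeric indicator values.
#' @param offset Additive shift used by the log candidate when any value is
#'   `<= 0`.
#' @return List `values` (transformed vector), `label` (`"identity"`,
#'   `"log"`, or `"log(x+<offset>)"`).
#' @export
transform_indicator <- function(values, offset = 10) {
  pick <- choose_distribution(values, offset = offset)
  if (pick$distribution == "normal") {
    return(list(values = values, label = "identity"))
  }
  if (pick$shift == 0) {
    list(values = log(values), label = "log")
  } else {
    list(values = log(values + pick$shift),
         label = sprintf("log(x+%g)", pick$shift))
  }
}

#' HDI mixed model for one change indicator
#'
#' Linear mixed model `indicator ~ HDI` with nested random intercepts for
#' continent and region-within-continent, fitted by REML via `lme4::lmer`.
#' The random structure absorbs spatial autocorrelation in national
#' indicator values. Incomplete cases (missing indicator, HDI, continent or
#' region) are dropped. A singular fit (a variance component estimated at
#' the zero boundary) is a valid converged result and is flagged.
#'
#' @param data Data frame with columns `value` (the, possibly transformed,
#'   indicator), `hdi`, `continent`, `region`.
#' @param transform_label Label recorded in the result (see
#'   [transform_indicator()]).
#' @return List of class `hdi_mixed_fit`: fixed effects `intercept`,
#'   `hdi_slope` with `se` and Wald `p`; `varprop` (named proportions
#'   `fixed`, `continent`, `region`, `unexplained` summing to 1); raw
#'   variance components; `singular`; `n`.
#' @export
fit_hdi_mixed_model <- function(data, transform_label = "identity") {
  need <- c("value", "hdi", "continent", "region")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (length(unique(data$continent)) < 2L) {
    stop("need at least 2 continents for the nested random structure")
  }
  # region coded uniquely within continent so (1 | continent / region) nests
  data$region <- interaction(data$continent, data$region, drop = TRUE)
  fit <- suppressMessages(lme4::lmer(
    value ~ hdi + (1 | continent / region), data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.rankZ = "ignore",
                                check.nobs.vs.nRE = "ignore")
  ))
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_cont <- vc$vcov[vc$grp == "continent"]
  var_reg <- vc$vcov[vc$grp == "region:continent"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  # fixed share: variance of the fixed-effect predictions (marginal-R2 style)
  var_fix <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  total <- var_fix + var_cont + var_reg + var_res
  if (total <= 0) stop("degenerate model: zero total variance")
  varprop <- c(fixed = var_fix, continent = var_cont, region = var_reg,
               unexplained = var_res) / total
  z <- sm[, "t value"]
  structure(list(
    intercept = sm[1L, "Estimate"], intercept_se = sm[1L, "Std. Error"],
    hdi_slope = sm[2L, "Estimate"], hdi_se = sm[2L, "Std. Error"],
    hdi_p = 2 * stats::pnorm(abs(z[2L]), lower.tail = FALSE),
    varprop = varprop,
    components = c(fixed = var_fix, continent = var_cont,
                   region = var_reg, residual = var_res),
    singular = lme4::isSingular(fit),
    transform = transform_label,
    n = nrow(data)
  ), class = "hdi_mixed_fit")
}

#' @export
print.hdi_mixed_fit <- function(x, ...) {
  cat(sprintf("HDI mixed model (transform: %s, n = %d%s)\n", x$transform,
              x$n, if (x$singular) ", singular fit" else ""))
  cat(sprintf("  intercept %.3f (%.3f), HDI slope %.3f (%.3f), p = %.3g\n",
              x$intercept, x$intercept_se, x$hdi_slope, x$hdi_se, x$hdi_p))
  cat(sprintf("  variance shares: fixed %.3f, continent %.3f, region %.3f, unexplained %.3f\n",
              x$varprop["fixed"], x$varprop["continent"],
              x$varprop["region"], x$varprop["unexplained"]))
  invisible(x)
}

#' Variance proportions of a fitted HDI mixed model
#'
#' @param fit An `hdi_mixed_fit`.
#' @return Named numeric vector (`fixed`, `continent`, `region`,
#'   `unexplained`) summing to 1.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "hdi_mixed_fit"))
  fit$varprop
}

#' Fit all six HDI mixed models
#'
#' For each metric (`S`, `J`) and indicator (onset, duration, rate) present
#' in the indicator table: transform the indicator by
#' [transform_indicator()], join country metadata (HDI, continent, region),
#' and fit the nested mixed model. Countries lacking HDI are dropped from
#' these models only.
#'
#' @param indicators Data frame from [indicator_table()] (possibly rbind-ed
#'   across metrics).
#' @param meta Country metadata with columns `country`, `hdi`, `continent`,
#'   `region`.
#' @param offset Log-candidate shift passed to [transform_indicator()].
#' @return Data frame shaped like a variance-components results table:
#'   `metric`, `indicator`, `transform`, `intercept`, `intercept_se`,
#'   `hdi_slope`, `hdi_se`, `hdi_p`, `prop_fixed`, `prop_continent`,
#'   `prop_region`, `prop_unexplained`, `n`.
#' @export
fit_socio_models <- function(indicators, meta, offset = 10) {
  ind_cols <- c(onset = 1L, duration = 2L, rate = 3L)
  rows <- list()
  for (metric in unique(indicators$metric)) {
    sub <- indicators[indicators$metric == metric, , drop = FALSE]
    m <- match(sub$country, meta$country)
    for (nm in names(ind_cols)) {
      tr <- transform_indicator(sub[[nm]], offset = offset)
      d <- data.frame(value = tr$values, hdi = meta$hdi[m],
                      continent = meta$continent[m],
                      region = meta$region[m], stringsAsFactors = FALSE)
      fit <- fit_hdi_mixed_model(d, transform_label = tr$label)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, indicator = ind_cols[[nm]], transform = fit$transform,
        intercept = fit$intercept, intercept_se = fit$intercept_se,
        hdi_slope = fit$hdi_slope, hdi_se = fit$hdi_se, hdi_p = fit$hdi_p,
        prop_fixed = fit$varprop[["fixed"]],
        prop_continent = fit$varprop[["continent"]],
        prop_region = fit$varprop[["region"]],
        prop_unexplained = fit$varprop[["unexplained"]],
        n = fit$n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
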