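#' Derive change indicators from a segmented fit
#'
#' Indicator 1 (onset) is the first breakpoint `psi1` — the year diversity
#' change began. Indicator 2 (duration) is `psi2 - psi1`, the length of the
#' change period in years. Indicator 3 (rate) is `b + c`, the slope of the
#' middle segment — the per-year change in the response between the
#' breakpoints.
#'
#' @param fit A converged [fit_segmented()] result.
#' @param country Optional country label to carry along.
#' @return List of class `indicator_set` with `country`, `metric`, `onset`,
#'   `duration`, `rate`.
#' @export
extract_indicators <- function(fit, country = NA_character_) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (!isTRUE(fit$converged)) {
    stop("cannot extract indicators from a non-converged fit (",
         fit$reason, ")")
  }
  structure(list(
    country = country, metric = fit$response_label,
    onset = fit$psi1, duration = fit$psi2 - fit$psi1,
    rate = fit$b + fit$c
  ), class = "indicator_set")
}

#' Indicator table from per-country fits
#'
#' Maps [fit_country_trends()] output to one indicator row per converged
#' country; non-converged countries are logged and skipped.
#'
#' @param fits Data frame from [fit_country_trends()].
#' @return Data frame `country,metric,onset,duration,rate`.
#' @export
indicator_table <- function(fits) {
  keep <- fits$converged
  skipped <- fits$country[!keep]
  if (length(skipped) > 0L) {
    message("indicators: skipping ", length(skipped),
            " non-converged countries: ",
            paste(utils::head(skipped, 10L), collapse = ", "),
            if (length(skipped) > 10L) ", ..." else "")
  }
  f <- fits[keep, , drop = FALSE]
  data.frame(
    country = f$country, metric = f$response,
    onset = f$psi1, duration = f$psi2 - f$psi1, rate = f$b + f$c,
    stringsAsFactors = FALSE
  )
}

# Gaussian and log-normal maximum-likelihood AICs. The log-normal candidate
# is fitted on log(x + shift); its log-likelihood carries the Jacobian term
# so the two AICs are comparable on the original scale.
normal_aic <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  if (s2 <= 0) return(Inf)
  -2 * (-n / 2 * (log(2 * pi * s2) + 1)) + 4
}

lognormal_aic <- function(x, shift) {
  y <- x + shift
  if (any(y <= 0)) return(Inf)
  ly <- log(y)
  n <- length(ly)
  s2 <- mean((ly - mean(ly))^2)
  if (s2 <= 0) return(Inf)
  ll <- -n / 2 * (log(2 * pi * s2) + 1) - sum(ly)
  -2 * ll + 4
}

#' Choose between normal and log-normal candidates
#'
#' Fits both distributions by maximum likelihood and compares AICs; the
#' log-normal is selected only when it wins by more than 2 AIC units
#' (candidates within Delta-AIC 2 are statistically indistinguishable, and
#' the normal/mean±sd convention is the default).
#' When any value is non-positive the log-normal candidate is fitted on
#' values shifted by `offset` (default +10, the convention used for rate
#' indicators that can be negative); the applied shift is recorded.
#'
#' @param values Numeric vector, `n >= 5` finite values.
#' @param offset Additive shift applied before the log candidate when any
#'   value is `<= 0`.
#' @return List `distribution` (`"normal"` or `"lognormal"`), `shift` (0 or
#'   `offset`), and the two AICs.
#' @export
choose_distribution <- function(values, offset = 10) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 finite values")
  shift <- if (any(values <= 0)) offset else 0
  a_norm <- normal_aic(values)
  a_lnorm <- lognormal_aic(values, shift)
  # parsimony rule: candidates within Delta-AIC 2 are indistinguishable, so
  # the log-normal must clearly win before mean±sd is abandoned
  list(
    distribution = if (a_lnorm < a_norm - 2) "lognormal" else "normal",
    shift = shift, aic_normal = a_norm, aic_lognormal = a_lnorm
  )
}

#' Distribution-aware cross-country summary of one indicator
#'
#' Reports mean +/- standard deviation when the values are best described as
#' normal, and median +/- median absolute deviation (raw m.a.d., no 1.4826
#' consistency factor) when log-normal wins, mirroring how national indicator
#' histograms are annotated. The normal-vs-log-normal choice is by AIC via
#' [choose_distribution()]. A constant vector is degenerate: mean +/- 0 is
#' returned with a warning.
#'
#' @param values Numeric indicator values across countries (`n >= 5`).
#' @param indicator Identifier (1 = onset, 2 = duration, 3 = rate) recorded
#'   in the output.
#' @param metric `"S"` or `"J"`.
#' @param offset Shift for the log-normal candidate when values are
#'   non-positive.
#' @return Data frame row: `metric`, `indicator`, `center`, `spread`,
#'   `center_kind` (`"mean±sd"` or `"median±mad"`), `distribution`, `n`.
#' @export
summarize_indicator <- function(values, indicator, metric = "S", offset = 10) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n >= 1L && stats::sd(values) == 0) {
    warning("degenerate distribution: all indicator values identical")
    return(data.frame(metric = metric, indicator = indicator,
                      center = values[1L], spread = 0,
                      center_kind = "mean±sd", distribution = "normal",
                      n = n, stringsAsFactors = FALSE))
  }
  pick <- choose_distribution(values, offset = offset)
  if (pick$distribution == "normal") {
    center <- mean(values); spread <- stats::sd(values)
    kind <- "mean±sd"
  } else {
    center <- stats::median(values)
    spread <- stats::median(abs(values - stats::median(values)))
    kind <- "median±mad"
  }
  data.frame(metric = metric, indicator = indicator, center = center,
             spread = spread, center_kind = kind,
             distribution = pick$distribution, n = n,
             stringsAsFactors = FALSE)
}

#' Summaries for all three indicators of one metric
#'
#' @param ind Data frame from [indicator_table()].
#' @param offset Passed to [summarize_indicator()].
#' @return Data frame with one row per indicator (onset, duration, rate).
#' @export
summarize_indicators <- function(ind, offset = 10) {
  metric <- unique(ind$metric)
  stopifnot(length(metric) == 1L)
  out <- rbind(
    summarize_indicator(ind$onset, 1L, metric, offset),
    summarize_indicator(ind$duration, 2L, metric, offset),
    summarize_indicator(ind$rate, 3L, metric, offset)
  )
  rownames(out) <- NULL
  out
}
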