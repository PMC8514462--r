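#' Ordinary least-squares linear trend
#'
#' Baseline model `y = a + b * year`: the starting point of the piecewise
#' fit and the reference against which the segmented fit is compared.
#'
#' @param years Strictly increasing numeric vector of years.
#' @param response Numeric response (`S` or `J'`), same length.
#' @return List with `a` (intercept), `b` (slope per year), `r2`, `p`
#'   (overall F-test), `sse`, `n`.
#' @export
fit_linear <- function(years, response) {
  check_series(years, response, min_n = 3L)
  if (length(unique(years)) < 2L) {
    stop("rank deficiency: `years` is constant")
  }
  fit <- stats::lm(response ~ years)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  list(
    a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
    r2 = sm$r.squared, p = unname(p),
    sse = sum(stats::residuals(fit)^2), n = length(years)
  )
}

check_series <- function(years, response, min_n) {
  if (length(years) != length(response)) {
    stop("`years` and `response` differ in length")
  }
  if (anyNA(years) || anyNA(response)) stop("series contains missing values")
  if (length(years) < min_n) {
    stop("series too short: need at least ", min_n, " observations")
  }
  if (is.unsorted(years, strictly = TRUE)) {
    stop("`years` must be strictly increasing")
  }
  invisible(NULL)
}

# Continuous two-breakpoint piecewise design: intercept, year, and hinge
# terms (year - psi)_+ whose coefficients are the slope differences c and d.
piecewise_design <- function(years, psi1, psi2) {
  cbind(1, years, pmax(years - psi1, 0), pmax(years - psi2, 0))
}

piecewise_ols <- function(years, response, psi1, psi2) {
  X <- piecewise_design(years, psi1, psi2)
  fit <- stats::lm.fit(X, response)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2),
       rank = fit$rank)
}

segment_support <- function(years, psi1, psi2) {
  c(sum(years <= psi1), sum(years > psi1 & years <= psi2), sum(years > psi2))
}

make_segmented_fit <- function(years, response, psi1, psi2, converged, reason,
                               iterations, response_label) {
  n <- length(years)
  a <- b <- cc <- d <- r2 <- p <- sse <- NA_real_
  if (converged) {
    ols <- piecewise_ols(years, response, psi1, psi2)
    if (ols$rank < 4L) {
      converged <- FALSE
      reason <- "rank-deficient piecewise design at fitted breakpoints"
    } else {
      a <- ols$coef[1L]; b <- ols$coef[2L]
      cc <- ols$coef[3L]; d <- ols$coef[4L]
      sse <- ols$sse
      sst <- sum((response - mean(response))^2)
      r2 <- if (sst > 0) 1 - sse / sst else NA_real_
      # overall F of the 5-regressor model (year, c, d, psi1, psi2) vs
      # intercept-only; breakpoints are counted as estimated parameters
      df1 <- 5L
      df2 <- n - 6L
      p <- if (df2 > 0L && sst > 0 && r2 < 1) {
        stats::pf((r2 / df1) / ((1 - r2) / df2), df1, df2, lower.tail = FALSE)
      } else if (!is.na(r2) && r2 >= 1) 0 else NA_real_
    }
  }
  structure(list(
    a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
    psi1 = if (converged) psi1 else NA_real_,
    psi2 = if (converged) psi2 else NA_real_,
    r2 = unname(r2), p_value = unname(p), sse = unname(sse),
    converged = converged, reason = reason, iterations = iterations,
    n = n, response_label = response_label
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Two-breakpoint segmented fit (", x$response_label, " ~ year), n = ",
      x$n, "\n", sep = "")
  if (!x$converged) {
    cat("  not converged:", x$reason, "\n")
  } else {
    cat(sprintf("  psi1 = %.2f, psi2 = %.2f\n", x$psi1, x$psi2))
    cat(sprintf("  slopes: %.4f | %.4f | %.4f (b, b+c, b+c+d)\n",
                x$b, x$b + x$c, x$b + x$c + x$d))
    cat(sprintf("  r2 = %.4f, p = %.3g\n", x$r2, x$p_value))
  }
  invisible(x)
}

#' Fit a two-breakpoint piecewise-linear model
#'
#' Fits `y = a + b*year + c*(year - psi1)_+ + d*(year - psi2)_+` by iterative
#' breakpoint relinearization: the design is augmented with gap indicator
#' terms `-I(year > psi)`, and each breakpoint is updated by the ratio of its
#' gap coefficient to its slope-difference coefficient until the update norm
#' falls below `tol`. The slope is `b` before `psi1`, `b + c` between the
#' breakpoints, and `b + c + d` after `psi2`; the fitted mean is continuous
#' at both breakpoints by construction.
#'
#' The fit is flagged non-converged (with a reason) if the iteration exceeds
#' `max_iter`, a slope-difference coefficient degenerates to zero (no
#' detectable breakpoint, e.g. exactly linear data), the breakpoints collapse
#' onto each other, leave the data range, or a segment ends up supported by
#' fewer than `min_support` observations.
#'
#' @inheritParams fit_linear
#' @param init_psi1,init_psi2 Initial breakpoint guesses (default 1975 and
#'   2000, suited to 1961-2017 national crop series).
#' @param tol Convergence tolerance on the breakpoint update norm.
#' @param max_iter Maximum relinearization iterations.
#' @param min_support Minimum observations per segment for a valid fit.
#' @param response_label `"S"` or `"J"`, recorded in the result.
#' @return Object of class `segmented_fit`: parameters `a`, `b`, `c`, `d`,
#'   `psi1`, `psi2`, plus `r2`, `p_value` (overall F vs intercept-only with 5
#'   model df), `sse`, `converged`, `reason`, `iterations`, `n`.
#' @seealso [grid_oracle()] for the exhaustive-search reference fit.
#' @export
fit_segmented <- function(years, response, init_psi1 = 1975, init_psi2 = 2000,
                          tol = 1e-6, max_iter = 100L, min_support = 2L,
                          response_label = "S") {
  check_series(years, response, min_n = 7L)
  rng <- range(years)
  if (!(init_psi1 < init_psi2)) stop("init_psi1 must be < init_psi2")
  # clamp initials into the open data range (short per-country series may not
  # bracket the defaults)
  eps <- max(1e-8, diff(rng) * 1e-6)
  psi <- c(
    min(max(init_psi1, rng[1L] + eps), rng[2L] - 3 * eps),
    min(max(init_psi2, rng[1L] + 2 * eps), rng[2L] - eps)
  )
  if (!(psi[1L] < psi[2L])) psi <- rng[1L] + diff(rng) * c(1, 2) / 3

  fail <- function(reason, it) {
    make_segmented_fit(years, response, NA, NA, FALSE, reason, it,
                       response_label)
  }
  # the relinearization can cycle between near-optimal breakpoint pairs, so
  # track the best-SSE pair and also accept convergence when the SSE stalls
  best_psi <- psi
  best_sse <- piecewise_ols(years, response, psi[1L], psi[2L])$sse
  stall <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    U1 <- pmax(years - psi[1L], 0)
    U2 <- pmax(years - psi[2L], 0)
    V1 <- -as.numeric(years > psi[1L])
    V2 <- -as.numeric(years > psi[2L])
    X <- cbind(1, years, U1, U2, V1, V2)
    fit <- stats::lm.fit(X, response)
    beta <- fit$coefficients[3:4]
    gam <- fit$coefficients[5:6]
    gam[is.na(gam)] <- 0
    if (anyNA(beta) || any(abs(beta) < 1e-10)) {
      return(fail("slope change degenerate (no identifiable breakpoint)", it))
    }
    step <- unname(gam / beta)
    proposal <- psi + step
    # step-halving safeguard: keep breakpoints ordered and inside the range
    h <- 1
    while ((proposal[1L] >= proposal[2L] ||
            proposal[1L] <= rng[1L] || proposal[2L] >= rng[2L]) && h > 1 / 64) {
      h <- h / 2
      proposal <- psi + h * step
    }
    if (proposal[1L] >= proposal[2L]) {
      return(fail("breakpoints collapsed", it))
    }
    if (proposal[1L] <= rng[1L] || proposal[2L] >= rng[2L]) {
      return(fail("breakpoint left the data range", it))
    }
    moved <- sqrt(sum((h * step)^2))
    psi <- proposal
    sse_now <- piecewise_ols(years, response, psi[1L], psi[2L])$sse
    if (sse_now < best_sse - 1e-9 * (1 + best_sse)) {
      best_sse <- sse_now
      best_psi <- psi
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (moved < tol) break
    if (stall >= 3L) {   # cycling without SSE improvement: take the best pair
      psi <- best_psi
      break
    }
    if (it >= max_iter) {
      return(fail("maximum iterations reached without breakpoint convergence", it))
    }
  }
  # deterministic local polish: the relinearization stops on its own
  # tolerance, so refine the breakpoint pair by direct SSE minimization
  obj <- function(p) {
    if (!(p[1L] < p[2L]) || p[1L] <= rng[1L] || p[2L] >= rng[2L]) return(Inf)
    if (any(segment_support(years, p[1L], p[2L]) < min_support)) return(Inf)
    piecewise_ols(years, response, p[1L], p[2L])$sse
  }
  if (is.finite(obj(psi))) {
    opt <- stats::optim(psi, obj, method = "Nelder-Mead",
                        control = list(maxit = 200L, reltol = 1e-12))
    if (is.finite(opt$value) && opt$value <= obj(psi)) psi <- unname(opt$par)
  }
  supp <- segment_support(years, psi[1L], psi[2L])
  if (any(supp < min_support)) {
    return(fail(sprintf("segment support below %d (got %s)", min_support,
                        paste(supp, collapse = "/")), it))
  }
  make_segmented_fit(years, response, psi[1L], psi[2L], TRUE, "ok", it,
                     response_label)
}

#' Exhaustive integer-grid breakpoint search
#'
#' Independent reference for [fit_segmented()]: fits the continuous piecewise
#' OLS model at every ordered pair of integer-year breakpoints leaving at
#' least `min_support` observations per segment, and returns the global SSE
#' minimizer. Ties are broken deterministically toward the earliest
#' `(psi1, psi2)`. Exact over its grid, so it bounds what the iterative
#' fitter should achieve on integer-breakpoint truths.
#'
#' @inheritParams fit_segmented
#' @return A `segmented_fit` (always converged unless no admissible pair
#'   exists).
#' @export
grid_oracle <- function(years, response, min_support = 2L,
                        response_label = "S") {
  check_series(years, response, min_n = 7L)
  cand <- seq.int(ceiling(min(years)), floor(max(years)))
  best <- NULL
  best_sse <- Inf
  for (p1 in cand) {
    if (sum(years <= p1) < min_support) next
    for (p2 in cand[cand > p1]) {
      supp <- segment_support(years, p1, p2)
      if (any(supp < min_support)) next
      sse <- piecewise_ols(years, response, p1, p2)$sse
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best <- c(p1, p2)
      }
    }
  }
  if (is.null(best)) {
    return(make_segmented_fit(years, response, NA, NA, FALSE,
                              "no admissible breakpoint pair", 0L,
                              response_label))
  }
  make_segmented_fit(years, response, best[1L], best[2L], TRUE, "ok", 0L,
                     response_label)
}

#' Fit segmented trends for every country in a diversity table
#'
#' Runs [fit_segmented()] on one response column (`S` or `J`) of a
#' [diversity_table()], country by country. Countries whose fit does not
#' converge are kept as explicit rows with `converged = FALSE` and `NA`
#' parameters rather than dropped. Per-country initial-breakpoint overrides
#' mirror the practice of hand-tuning starting values for countries with a
#' shortened data range; overrides are data, not code.
#'
#' @param div Output of [diversity_table()].
#' @param response `"S"` or `"J"`. For `"J"`, country-years with undefined
#'   evenness (`S = 1`) are excluded before fitting.
#' @param init_psi1,init_psi2 Default breakpoint initials.
#' @param overrides Named list `country -> c(psi1, psi2)` of per-country
#'   initial values. Unknown country names are an error.
#' @param min_years Minimum observations for a country to be attempted.
#' @return Data frame with one row per country:
#'   `country,response,a,b,c,d,psi1,psi2,r2,p,converged,n,reason`.
#' @export
fit_country_trends <- function(div, response = c("S", "J"),
                               init_psi1 = 1975, init_psi2 = 2000,
                               overrides = NULL, min_years = 7L) {
  response <- match.arg(response)
  if (response == "J") div <- div[div$J_defined, , drop = FALSE]
  countries <- sort(unique(div$country))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), countries)
    if (length(unknown) > 0L) {
      stop("breakpoint override for unknown country: ",
           paste(unknown, collapse = ", "))
    }
  }
  rows <- lapply(countries, function(ctry) {
    d <- div[div$country == ctry, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    y <- d[[response]]
    init <- c(init_psi1, init_psi2)
    if (!is.null(overrides) && ctry %in% names(overrides)) {
      init <- overrides[[ctry]]
    }
    fit <- if (nrow(d) >= min_years) {
      tryCatch(
        fit_segmented(d$year, y, init[1L], init[2L],
                      response_label = response),
        error = function(e) {
          make_segmented_fit(d$year, y, NA, NA, FALSE, conditionMessage(e),
                             0L, response)
        })
    } else {
      structure(list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                     psi1 = NA_real_, psi2 = NA_real_, r2 = NA_real_,
                     p_value = NA_real_, sse = NA_real_, converged = FALSE,
                     reason = "series shorter than min_years",
                     iterations = 0L, n = nrow(d), response_label = response),
                class = "segmented_fit")
    }
    data.frame(country = ctry, response = response,
               a = fit$a, b = fit$b, c = fit$c, d = fit$d,
               psi1 = fit$psi1, psi2 = fit$psi2, r2 = fit$r2,
               p = fit$p_value, converged = fit$converged, n = fit$n,
               reason = fit$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
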