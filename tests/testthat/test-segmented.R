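test_that("fit_linear recovers exact and noisy lines", {
  yrs <- 1961:2017
  f <- fit_linear(yrs, 2 + 0.5 * yrs)
  expect_equal(f$b, 0.5)
  expect_equal(f$r2, 1)
  expect_equal(fit_linear(yrs, rep(4, 57))$b, 0)
  # closed-form OLS oracle on a seeded noisy line
  set.seed(21)
  y <- 3 + 0.8 * yrs + rnorm(57, 0, 1)
  f2 <- fit_linear(yrs, y)
  b_hat <- sum((yrs - mean(yrs)) * (y - mean(y))) / sum((yrs - mean(yrs))^2)
  expect_equal(f2$b, b_hat)
  expect_lt(abs(f2$b - 0.8), 0.1)
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)),
               "rank|strictly increasing")
  expect_error(fit_linear(c(2000, 1999, 2001), 1:3), "strictly increasing")
})

test_that("fit_segmented recovers a noiseless piecewise truth", {
  yrs <- 1961:2017
  f <- fit_segmented(yrs, flat_rise_flat(yrs))
  expect_true(f$converged)
  expect_equal(f$psi1, 1980, tolerance = 1e-4)
  expect_equal(f$psi2, 1995, tolerance = 1e-4)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(f$b + f$c, 1, tolerance = 1e-4)
  expect_equal(f$b + f$c + f$d, 0, tolerance = 1e-4)
  expect_equal(f$r2, 1, tolerance = 1e-8)
})

test_that("exactly linear data is flagged as having no identifiable breakpoint", {
  yrs <- 1961:2017
  f <- fit_segmented(yrs, 2 + 0.5 * yrs)
  expect_false(f$converged)
  expect_match(f$reason, "degenerate")
})

test_that("validation errors are explicit", {
  expect_error(fit_segmented(c(2000, 1999, 2001, 2002, 2003, 2004, 2005),
                             rnorm(7)), "strictly increasing")
  expect_error(fit_segmented(1961:1965, rnorm(5)), "too short")
  expect_error(fit_segmented(1961:2017, rnorm(57), init_psi1 = 2001,
                             init_psi2 = 2000), "init_psi1")
})

test_that("fitted piecewise mean is continuous at both breakpoints", {
  set.seed(22)
  yrs <- 1961:2017
  for (i in 1:5) {
    y <- flat_rise_flat(yrs) + rnorm(57, 0, 1)
    f <- fit_segmented(yrs, y)
    expect_true(f$converged)
    predfun <- function(t) {
      f$a + f$b * t + f$c * pmax(t - f$psi1, 0) + f$d * pmax(t - f$psi2, 0)
    }
    eps <- 1e-9
    expect_lt(abs(predfun(f$psi1 - eps) - predfun(f$psi1 + eps)), 1e-6)
    expect_lt(abs(predfun(f$psi2 - eps) - predfun(f$psi2 + eps)), 1e-6)
  }
})

test_that("segmented SSE is nested below linear SSE", {
  set.seed(23)
  yrs <- 1961:2017
  for (i in 1:8) {
    y <- 20 + 0.3 * (yrs - 1961) + rnorm(57, 0, 2)
    f <- fit_segmented(yrs, y)
    if (!f$converged) next
    expect_lte(f$sse, fit_linear(yrs, y)$sse + 1e-8)
  }
})

test_that("grid_oracle returns the exhaustive argmin with earliest-pair tie-break", {
  yrs <- 2000:2009
  set.seed(24)
  y <- c(1, 1.2, 0.9, 3, 5, 7, 9, 9.1, 8.9, 9)
  g <- grid_oracle(yrs, y)
  expect_true(g$converged)
  # enumerate every admissible integer pair and verify global minimality
  best_sse <- Inf
  for (p1 in 2000:2009) for (p2 in 2000:2009) {
    if (p2 <= p1) next
    supp <- c(sum(yrs <= p1), sum(yrs > p1 & yrs <= p2), sum(yrs > p2))
    if (any(supp < 2)) next
    X <- cbind(1, yrs, pmax(yrs - p1, 0), pmax(yrs - p2, 0))
    sse <- sum(lm.fit(X, y)$residuals^2)
    expect_gte(sse, g$sse - 1e-9)
    best_sse <- min(best_sse, sse)
  }
  expect_equal(g$sse, best_sse)
})

test_that("grid_oracle nails the noiseless truth exactly", {
  yrs <- 1961:2017
  g <- grid_oracle(yrs, flat_rise_flat(yrs))
  expect_equal(c(g$psi1, g$psi2), c(1980, 1995))
  expect_equal(g$b + g$c, 1, tolerance = 1e-10)
  expect_lt(g$sse, 1e-18)
})

test_that("iterative fitter tracks the grid oracle on seeded noisy series", {
  yrs <- 1961:2017
  set.seed(25)
  n_ok <- 0
  for (i in 1:10) {
    y <- flat_rise_flat(yrs) + rnorm(57, 0, 1)
    f <- fit_segmented(yrs, y)
    g <- grid_oracle(yrs, y)
    expect_true(f$converged)
    # continuous-psi fit may beat the integer grid; never much worse
    expect_lte(f$sse, g$sse * 1.01)
    expect_lte(abs(f$psi1 - g$psi1), 2)
    expect_lte(abs(f$psi2 - g$psi2), 2)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 10)
})

test_that("breakpoint recovery degrades gracefully with noise", {
  yrs <- 1961:2017
  for (sigma in c(0, 0.5, 1)) {
    set.seed(100 + sigma * 10)
    err1 <- err2 <- numeric(12)
    for (i in 1:12) {
      y <- flat_rise_flat(yrs) + rnorm(57, 0, sigma)
      f <- fit_segmented(yrs, y)
      expect_true(f$converged)
      err1[i] <- abs(f$psi1 - 1980); err2[i] <- abs(f$psi2 - 1995)
    }
    tol <- if (sigma == 0) 1 else 2
    expect_lte(median(err1), tol)
    expect_lte(median(err2), tol)
  }
})

test_that("fit_country_trends keeps non-converged countries as explicit rows", {
  yrs <- 1961:2017
  div <- rbind(
    data.frame(country = "Good", year = yrs, S = flat_rise_flat(yrs),
               H = 1, J = 0.9, J_defined = TRUE, total_area = 1),
    data.frame(country = "Linear", year = yrs, S = 2 + 0.5 * (yrs - 1961),
               H = 1, J = 0.9, J_defined = TRUE, total_area = 1),
    data.frame(country = "Short", year = 1961:1964, S = c(3, 4, 5, 6),
               H = 1, J = 0.9, J_defined = TRUE, total_area = 1)
  )
  fits <- fit_country_trends(div, "S")
  expect_equal(nrow(fits), 3L)
  expect_equal(fits$converged, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(fits$psi1[!fits$converged])))
  expect_error(fit_country_trends(div, "S", overrides = list(Nowhere = c(1970, 1990))),
               "unknown country")
})

test_that("per-country breakpoint-initial overrides are honoured", {
  yrs <- 1961:2017
  div <- data.frame(country = "A", year = yrs,
                    S = flat_rise_flat(yrs, psi1 = 1970, psi2 = 1976),
                    H = 1, J = 0.9, J_defined = TRUE, total_area = 1)
  fits <- fit_country_trends(div, "S",
                             overrides = list(A = c(1969, 1978)))
  expect_true(fits$converged)
  expect_equal(fits$psi1, 1970, tolerance = 0.1)
  expect_equal(fits$psi2, 1976, tolerance = 0.1)
})
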