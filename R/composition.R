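#' Country-by-year community matrix
#'
#' Builds the samples-by-crop-groups abundance matrix from harmonized
#' records, with harvested area (ha) as the abundance proxy. Rows are
#' `country_year` samples; columns are the union of crop groups, absent
#' groups stored as zeros.
#'
#' @param records Harmonized record data frame.
#' @return Numeric matrix with rownames `country_year`; attributes `country`
#'   and `year` give the sample factors in row order.
#' @export
community_matrix <- function(records) {
  check_records(records)
  records <- records[records$area_ha > 0, , drop = FALSE]
  sample_id <- paste(records$country, records$year, sep = "_")
  groups <- sort(unique(records$crop_group))
  ids <- unique(sample_id)
  mat <- matrix(0, nrow = length(ids), ncol = length(groups),
                dimnames = list(ids, groups))
  mat[cbind(match(sample_id, ids), match(records$crop_group, groups))] <-
    records$area_ha
  first <- !duplicated(sample_id)
  attr(mat, "country") <- records$country[first]
  attr(mat, "year") <- records$year[first]
  mat
}

#' Number of unique pairwise dissimilarities
#'
#' `n * (n - 1) / 2`, computed in double precision so large sample counts do
#' not overflow.
#'
#' @param n Number of samples.
#' @return Pair count as a double.
#' @export
pair_count <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`: the Manhattan
#' distance between two samples scaled by their summed abundance. 0 for
#' identical samples, 1 for samples sharing no crop group.
#'
#' @param mat Community matrix (samples in rows, non-negative cells, every
#'   row with positive total).
#' @return Condensed `dist` object with `n(n-1)/2` entries.
#' @export
bray_curtis_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples")
  if (any(mat < 0)) stop("negative abundances are invalid")
  tot <- rowSums(mat)
  if (any(tot == 0)) {
    stop("validation error: sample(s) with all-zero abundances: ",
         paste(utils::head(rownames(mat)[tot == 0], 5L), collapse = ", "))
  }
  num <- stats::dist(mat, method = "manhattan")
  n <- nrow(mat)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  den <- tot[ij[, 1L]] + tot[ij[, 2L]]
  structure(as.vector(num) / den, class = "dist", Size = n,
            Labels = rownames(mat), Diag = FALSE, Upper = FALSE,
            method = "bray")
}

#' Kruskal stress-1 of a configuration
#'
#' Stress of embedding coordinates against a target dissimilarity matrix:
#' configuration distances are monotonically regressed on the
#' dissimilarities (pooled-adjacent-violators) and
#' `sqrt(sum((dhat - dconf)^2) / sum(dconf^2))` is returned. Used as an
#' independent check on the NMDS optimizer.
#'
#' @param d `dist` object of target dissimilarities.
#' @param coords Numeric coordinate matrix, one row per sample.
#' @return Stress-1 value in `[0, 1]`.
#' @export
stress1 <- function(d, coords) {
  dv <- as.vector(d)
  cv <- as.vector(stats::dist(coords))
  o <- order(dv)
  fit <- stats::isoreg(dv[o], cv[o])
  dhat <- numeric(length(dv))
  dhat[o] <- fit$yf
  sqrt(sum((cv - dhat)^2) / sum(cv^2))
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions minimizing Kruskal
#' stress-1, starting from the classical metric MDS configuration plus
#' `n_starts - 1` seeded random starts; the lowest-stress solution is
#' returned. The optimizer is `vegan::monoMDS` (monotone regression with
#' coordinate updates); determinism is guaranteed by seeding every start.
#'
#' @param d `dist` object.
#' @param k Embedding dimension (default 2); must be `< n`.
#' @param n_starts Total number of starts (classical init counts as one).
#' @param seed Integer seed controlling the random starts.
#' @return List with `points` (n x k matrix), `stress` (stress-1 of the best
#'   start), `start` (index of the winning start, 1 = classical init).
#' @export
nmds_ordination <- function(d, k = 2L, n_starts = 4L, seed = 1L) {
  n <- attr(d, "Size")
  if (k >= n) stop("embedding dimension k must be smaller than sample count")
  init <- stats::cmdscale(d, k = k, add = TRUE)$points
  runs <- vector("list", n_starts)
  runs[[1L]] <- vegan::monoMDS(d, y = init, k = k, model = "global")
  if (n_starts > 1L) {
    for (s in 2:n_starts) {
      set.seed(seed + s)
      y0 <- matrix(stats::rnorm(n * k), n, k)
      runs[[s]] <- vegan::monoMDS(d, y = y0, k = k, model = "global")
    }
  }
  stresses <- vapply(runs, function(r) r$stress, numeric(1))
  best <- which.min(stresses)
  pts <- runs[[best]]$points
  rownames(pts) <- attr(d, "Labels")
  list(points = pts, stress = stresses[best], start = best,
       all_stresses = stresses)
}

# Gower-centered inner-product matrix from squared dissimilarities
# (McArdle & Anderson decomposition); its trace is the total sum of squares.
gower_matrix <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational MANOVA on a dissimilarity matrix
#'
#' Sequential (entry-order, Type-I) decomposition of the total sum of
#' squares of a dissimilarity matrix among model terms, with pseudo-F
#' statistics and significance by free permutation of sample labels. Terms
#' are added cumulatively; each term's SS is the increase in explained trace
#' of the Gower-centered matrix. `year`-type numeric covariates contribute
#' 1 df; factors contribute `levels - 1`; an interaction `a:b` contributes
#' the extra rank beyond its margins. p-values use the count estimator
#' `(b + 1) / (n_perm + 1)`, so with 99 permutations they fall on the grid
#' 0.01, 0.02, ..., 1.
#'
#' @param d `dist` object of dissimilarities among samples.
#' @param data Data frame of sample covariates, rows aligned with `d`.
#' @param terms Character vector of term labels (columns of `data` or `a:b`
#'   interactions), in the order they enter the model. Default
#'   `c("year", "country", "year:country")` with year numeric.
#' @param n_perm Number of permutations (default 99).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame of class `permanova_table`: one row per term plus
#'   `Residuals` and `Total`, columns `term`, `df`, `SS`, `MS`, `F`, `r2`,
#'   `p`.
#' @export
permanova <- function(d, data,
                      terms = c("year", "country", "year:country"),
                      n_perm = 99L, seed = 1L) {
  n <- attr(d, "Size")
  stopifnot(nrow(data) == n)
  G <- gower_matrix(d)
  ss_total <- sum(diag(G))

  # cumulative designs: intercept, then + term 1, + term 2, ...
  forms <- lapply(seq_along(terms), function(i) {
    stats::as.formula(paste("~", paste(terms[seq_len(i)], collapse = " + ")))
  })
  Xs <- lapply(forms, function(f) stats::model.matrix(f, data = data))
  Hs <- lapply(Xs, hat_matrix)
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1))
  dfs <- diff(c(1L, ranks))
  if (any(dfs == 0L)) {
    stop("confounded model term (zero df): ",
         paste(terms[dfs == 0L], collapse = ", "))
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L) stop("confounded model: zero residual degrees of freedom")

  explained <- function(Gm) {
    tr <- vapply(Hs, function(H) sum(H * Gm), numeric(1))
    diff(c(0, tr))
  }
  ss <- explained(G)
  ss_res <- ss_total - sum(ss)
  ms <- ss / dfs
  ms_res <- ss_res / df_res
  fstat <- ms / ms_res

  set.seed(seed)
  eps <- sqrt(.Machine$double.eps)   # tie guard for permuted-F comparisons
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Gp <- G[perm, perm]
    ssp <- explained(Gp)
    fp <- (ssp / dfs) / ((ss_total - sum(ssp)) / df_res)
    exceed <- exceed + (fp >= fstat - eps)
  }
  pval <- (exceed + 1) / (n_perm + 1)

  out <- data.frame(
    term = c(terms, "Residuals", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    MS = c(ms, ms_res, NA_real_),
    F = c(fstat, NA_real_, NA_real_),
    r2 = c(ss, ss_res, ss_total) / ss_total,
    p = c(pval, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova_table", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' Per-year multivariate dispersion
#'
#' Auxiliary diagnostic for the shrinking-dispersion pattern: mean distance
#' of each year's samples to that year's spatial centroid (via
#' `vegan::betadisper`).
#'
#' @param d `dist` object.
#' @param years Year label per sample.
#' @return Data frame `year`, `mean_dist_to_centroid`, `n_samples`.
#' @export
year_dispersion <- function(d, years) {
  bd <- vegan::betadisper(d, group = factor(years), type = "centroid")
  dists <- tapply(bd$distances, factor(years), mean)
  data.frame(
    year = as.integer(names(dists)),
    mean_dist_to_centroid = as.numeric(dists),
    n_samples = as.integer(table(factor(years))),
    stringsAsFactors = FALSE
  )
}
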