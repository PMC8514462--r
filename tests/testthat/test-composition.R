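test_that("community matrix places areas and keeps absences as zeros", {
  rec <- data.frame(
    country = c("A", "A", "B"), year = c(2000, 2000, 2000),
    crop_group = c("Wheat", "Maize", "Wheat"),
    area_ha = c(5, 2, 7), stringsAsFactors = FALSE)
  cm <- community_matrix(rec)
  expect_equal(dim(cm), c(2L, 2L))
  expect_equal(cm["A_2000", "Maize"], 2)
  expect_equal(cm["B_2000", "Maize"], 0)
  expect_equal(attr(cm, "country"), c("A", "B"))
})

test_that("Bray-Curtis matches hand computations", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  d <- as.matrix(bray_curtis_matrix(m))
  expect_equal(d["a", "b"], 1)      # disjoint
  expect_equal(d["a", "c"], 0)      # identical
  m2 <- rbind(x = c(2, 1), y = c(1, 1))
  expect_equal(as.vector(bray_curtis_matrix(m2)), 0.2)  # (|1|+|0|)/(3+2)
  expect_error(bray_curtis_matrix(rbind(c(1, 1), c(0, 0))), "all-zero")
  expect_error(bray_curtis_matrix(rbind(c(1, -1), c(1, 1))), "negative")
})

test_that("Bray-Curtis agrees with the vegan reference on random matrices", {
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rexp(15 * 7), 15, 7)
    m[sample(length(m), 20)] <- 0
    expect_equal(as.vector(bray_curtis_matrix(m)),
                 as.vector(vegan::vegdist(m, method = "bray")))
  }
})

test_that("pair count is n(n-1)/2 and stored pairs match", {
  set.seed(42)
  m <- matrix(rexp(11 * 4), 11, 4)
  expect_equal(length(as.vector(bray_curtis_matrix(m))), pair_count(11))
  expect_equal(pair_count(6), 15)
})

test_that("NMDS embeds planar configurations with near-zero stress", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- dist(sq)
  o <- nmds_ordination(d, k = 2, n_starts = 2, seed = 1)
  expect_lt(o$stress, 0.01)
  expect_lt(stress1(d, o$points), 0.01)
})

test_that("duplicated samples land on coincident coordinates", {
  set.seed(43)
  m <- matrix(rexp(6 * 5), 6, 5)
  m <- rbind(m, m[3, ])          # duplicate sample 3 as sample 7
  d <- bray_curtis_matrix(m)
  o <- nmds_ordination(d, k = 2, n_starts = 2, seed = 2)
  expect_lt(sqrt(sum((o$points[3, ] - o$points[7, ])^2)), 1e-5)
})

test_that("NMDS is bit-stable under a fixed seed and beats its metric start", {
  set.seed(44)
  m <- matrix(rexp(20 * 6), 20, 6)
  d <- bray_curtis_matrix(m)
  o1 <- nmds_ordination(d, seed = 7)
  o2 <- nmds_ordination(d, seed = 7)
  expect_identical(o1$stress, o2$stress)
  expect_identical(o1$points, o2$points)
  init <- cmdscale(d, k = 2, add = TRUE)$points
  expect_lte(stress1(d, o1$points), stress1(d, init) + 1e-10)
  expect_error(nmds_ordination(d, k = 20), "smaller than sample count")
})

test_that("permanova reproduces the vegan adonis2 sequential decomposition", {
  set.seed(45)
  m <- matrix(rexp(24 * 8), 24, 8)
  d <- bray_curtis_matrix(m)
  dat <- data.frame(year = rep(1:6, 4), country = factor(rep(LETTERS[1:4], each = 6)))
  p <- permanova(d, dat, n_perm = 99, seed = 1)
  a <- vegan::adonis2(d ~ year + country + year:country, data = dat,
                      permutations = 99, by = "terms")
  expect_equal(p$SS[1:3], a$SumOfSqs[1:3])
  expect_equal(p$df[1:4], a$Df[1:4])
  expect_equal(p$F[1:3], a$F[1:3])
  expect_equal(p$r2[1:4], a$R2[1:4])
  # year enters as a single-df numeric covariate
  expect_equal(p$df[p$term == "year"], 1L)
})

test_that("permanova SS decomposition conserves total SS and is order-stable", {
  set.seed(46)
  m <- matrix(rexp(18 * 5), 18, 5)
  d <- bray_curtis_matrix(m)
  dat <- data.frame(year = rep(1:6, 3), country = factor(rep(c("A", "B", "C"), each = 6)))
  p <- permanova(d, dat, n_perm = 19, seed = 1)
  tot <- p$SS[p$term == "Total"]
  expect_equal(sum(p$SS[1:4]), tot, tolerance = 1e-9)
  expect_equal(sum(p$r2[1:4]), 1, tolerance = 1e-9)
  # reordering samples (with their labels) leaves the SS terms unchanged
  perm <- sample(18)
  m2 <- m[perm, ]; dat2 <- dat[perm, ]
  p2 <- permanova(bray_curtis_matrix(m2), dat2, n_perm = 19, seed = 1)
  expect_equal(p2$SS, p$SS, tolerance = 1e-9)
  # p-values live on the (b+1)/(n_perm+1) grid
  expect_equal(p$p[1:3] * 20, round(p$p[1:3] * 20))
  expect_true(all(p$p[1:3] >= 0.05 & p$p[1:3] <= 1))
})

test_that("pseudo-F equals the full-enumeration oracle on a 6-sample fixture", {
  set.seed(47)
  m <- rbind(matrix(rexp(3 * 4, rate = 1), 3, 4),
             matrix(rexp(3 * 4, rate = 0.2), 3, 4))
  d <- bray_curtis_matrix(m)
  groups <- factor(rep(c("g1", "g2"), each = 3))
  p <- permanova(d, data.frame(group = groups), terms = "group",
                 n_perm = 1999, seed = 1)
  f_obs <- p$F[1]
  expect_equal(f_obs, pseudo_f_bruteforce(d, groups))
  # exact p by enumerating all 20 assignments of 3-vs-3 labels
  combs <- combn(6, 3)
  f_all <- apply(combs, 2, function(idx) {
    g <- factor(ifelse(seq_len(6) %in% idx, "g1", "g2"))
    pseudo_f_bruteforce(d, g)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_lt(abs(p$p[1] - p_exact), 0.05)
})

test_that("well-separated clusters yield dominant group r2", {
  set.seed(48)
  m <- rbind(matrix(abs(rnorm(5 * 6, 100, 1)), 5, 6),
             matrix(abs(rnorm(5 * 6, 1, 0.1)), 5, 6))
  d <- bray_curtis_matrix(m)
  p <- permanova(d, data.frame(group = factor(rep(1:2, each = 5))),
                 terms = "group", n_perm = 99, seed = 1)
  expect_gt(p$r2[1], 0.9)
  expect_lte(p$p[1], 0.05)
})

test_that("confounded designs raise explicit errors", {
  set.seed(49)
  m <- matrix(rexp(8 * 4), 8, 4)
  d <- bray_curtis_matrix(m)
  dat <- data.frame(a = factor(rep(1:2, each = 4)),
                    b = factor(rep(1:2, each = 4)))  # b aliases a
  expect_error(permanova(d, dat, terms = c("a", "b"), n_perm = 9),
               "confounded")
})

test_that("per-year dispersion column tracks a shrinking spread", {
  set.seed(50)
  y1 <- matrix(rexp(8 * 5, rate = 0.2), 8, 5)        # diffuse year
  y2 <- sweep(matrix(1, 8, 5), 2, c(5, 4, 3, 2, 1), "*") +
    matrix(rnorm(40, 0, 0.01), 8, 5)                  # tight year
  m <- rbind(y1, abs(y2))
  d <- bray_curtis_matrix(m)
  disp <- year_dispersion(d, rep(c(1961, 2017), each = 8))
  expect_equal(nrow(disp), 2L)
  expect_gt(disp$mean_dist_to_centroid[disp$year == 1961],
            disp$mean_dist_to_centroid[disp$year == 2017])
})
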