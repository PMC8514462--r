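# Fixtures built in code; all randomness under explicit seeds.

# Long-format records: every listed country x year x crop combination.
make_records <- function(countries, years, crops, area = 10) {
  g <- expand.grid(country = countries, year = years, crop_group = crops,
                   stringsAsFactors = FALSE)
  g$area_ha <- rep_len(area, nrow(g))
  g[order(g$country, g$year, g$crop_group), ]
}

# FAOSTAT-dialect CSV on disk; returns the path.
write_faostat_fixture <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "production.csv")
  cropdiv::write_faostat_csv(records, path)
  path
}

# Noiseless flat/rise/flat richness trajectory used across segmented tests:
# 20 until 1980, +1/yr to 1995, then 35.
flat_rise_flat <- function(years = 1961:2017, S0 = 20, psi1 = 1980,
                           psi2 = 1995, rate = 1) {
  S0 + rate * pmax(years - psi1, 0) - rate * pmax(years - psi2, 0)
}

# Direct pseudo-F from a distance matrix for a one-factor design, computed
# from within/between squared distances (independent of the Gower-matrix
# route used by permanova()).
pseudo_f_bruteforce <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ss_total <- sum(dm[lower.tri(dm)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  (ss_between / (a - 1)) / (ss_within / (n - a))
}
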