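test_that("element filter and malformed rows are handled on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "prod.csv")
  write.csv(data.frame(
    Area = c("A", "A", "A", "B"),
    Item = c("Wheat", "Wheat", "Maize", "Wheat"),
    Element = c("Area harvested", "Production", "Area harvested",
                "Area harvested"),
    Year = c(2000, 2000, 2001, 2002),
    Unit = "ha",
    Value = c("10", "99", "", "5")
  ), path, row.names = FALSE)
  rec <- suppressMessages(read_production_table(path))
  expect_equal(nrow(rec), 2L)       # Production row and empty value dropped
  rep <- attr(rec, "ingest_report")
  expect_equal(rep$element_filtered, 1L)
  expect_equal(rep$skipped_bad_value, 1L)
  expect_equal(rec$area_ha, c(10, 5))
})

test_that("missing columns and empty results are explicit errors", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  write.csv(data.frame(Area = "A", Year = 2000, Value = 1), path,
            row.names = FALSE)
  expect_error(read_production_table(path), "required column")
  path2 <- file.path(dir, "empty.csv")
  write.csv(data.frame(Area = "A", Item = "Wheat", Element = "Production",
                       Year = 2000, Unit = "ha", Value = 1), path2,
            row.names = FALSE)
  expect_error(suppressMessages(read_production_table(path2)), "empty input")
  expect_error(read_production_table(file.path(dir, "nope.csv")),
               "does not exist")
})

test_that("fixture of 5 countries x 10 years x 6 crops yields 300 records", {
  rec <- make_records(paste0("C", 1:5), 2001:2010, paste0("crop", 1:6))
  path <- write_faostat_fixture(rec)
  got <- suppressMessages(read_production_table(path,
                                                year_range = c(2001, 2010)))
  expect_equal(nrow(got), 300L)
})

test_that("crop-group harmonization merges, renames and removes as configured", {
  rec <- data.frame(
    country = "A", year = 2000,
    crop_group = c("Cottonlint", "Cottonseed", "Palmkernels", "Coir",
                   "Wheat", "Fruitpomenes", "Fruitstonenes", "Grainmixed",
                   "Mushroomsandtruffles"),
    area_ha = c(10, 5, 7, 3, 9, 1, 1, 1, 1), stringsAsFactors = FALSE)
  out <- harmonize_crop_groups(rec)
  expect_setequal(out$crop_group, c("Seedcotton", "Oilpalmfruit", "Wheat"))
  expect_equal(out$area_ha[out$crop_group == "Seedcotton"], 15)
  expect_equal(out$area_ha[out$crop_group == "Oilpalmfruit"], 7)
  expect_equal(out$area_ha[out$crop_group == "Wheat"], 9)
  rep <- attr(out, "harmonization_report")
  expect_equal(rep$merged_rows, 2L)
  expect_equal(rep$renamed_rows, 1L)
  expect_equal(rep$removed_rows, 5L)
})

test_that("harmonization conserves area apart from removed labels, and is idempotent", {
  set.seed(101)
  crops <- c("Cottonlint", "Cottonseed", "Palmkernels", "Wheat", "Maize",
             "Coir", "Grainmixed")
  rec <- make_records(c("A", "B"), 2000:2002, crops,
                      area = runif(2 * 3 * 7, 1, 100))
  out <- harmonize_crop_groups(rec)
  removed <- rec$crop_group %in% c("Fruitpomenes", "Fruitstonenes",
                                   "Grainmixed", "Mushroomsandtruffles",
                                   "Coir")
  expect_equal(sum(out$area_ha), sum(rec$area_ha[!removed]))
  # per-country-year totals also conserved
  tot_in <- tapply(rec$area_ha[!removed],
                   paste(rec$country, rec$year)[!removed], sum)
  tot_out <- tapply(out$area_ha, paste(out$country, out$year), sum)
  expect_equal(unname(tot_out[names(tot_in)]), unname(tot_in))
  # unique keys after harmonization
  expect_false(anyDuplicated(
    paste(out$country, out$year, out$crop_group)) > 0)
  # idempotent on already-clean data
  again <- harmonize_crop_groups(out)
  expect_equal(again[order(again$country, again$year, again$crop_group), ],
               out[order(out$country, out$year, out$crop_group), ],
               ignore_attr = TRUE)
})

test_that("country filtering drops dissolved states and reports retention", {
  rec <- make_records(c("Yugoslavia", "France", "Ghana", "USSR", "Peru"),
                      2000:2001, c("Wheat", "Maize"))
  out <- filter_countries(rec, c("France", "Ghana", "Peru"))
  expect_false("Yugoslavia" %in% out$country)
  rep <- attr(out, "country_report")
  expect_equal(length(rep$retained), 3L)
  expect_setequal(rep$dropped, c("Yugoslavia", "USSR"))
  # identity when the valid set equals the observed set
  idem <- filter_countries(rec, unique(rec$country))
  expect_equal(nrow(idem), nrow(rec))
  expect_error(filter_countries(rec, character()), "configuration error")
})

test_that("aliases normalize country keys before filtering", {
  rec <- make_records(c("Cote dIvoire", "France"), 2000, "Wheat")
  out <- filter_countries(rec, c("Ivory Coast", "France"),
                          aliases = c("Cote dIvoire" = "Ivory Coast"))
  expect_setequal(unique(out$country), c("Ivory Coast", "France"))
})

test_that("FAOSTAT write/read round-trip preserves records", {
  rec <- make_records(c("A", "B"), 2000:2004, paste0("crop", 1:3),
                      area = seq_len(30))
  path <- write_faostat_fixture(rec)
  got <- suppressMessages(read_production_table(path,
                                                year_range = c(2000, 2004)))
  got <- got[order(got$country, got$year, got$crop_group), ]
  rec <- rec[order(rec$country, rec$year, rec$crop_group), ]
  expect_equal(got$area_ha, rec$area_ha, ignore_attr = TRUE)
  expect_equal(got$crop_group, rec$crop_group, ignore_attr = TRUE)
})
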