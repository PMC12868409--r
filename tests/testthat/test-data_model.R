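test_that("exposure-year mapping follows each log's exposure origin", {
  design <- toy_design()
  rec <- data.frame(
    log_id = c("L1", "L2", "L2", "L2", "L3"),
    calendar_year = c(2013, 2013, 2015, 2015, 2014),
    species_id = c("sA", "sA", "sB", "sB", "sC"),
    count = c(2, 1, 2, 3, 4))
  rp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, rp, row.names = FALSE)
  write_design(design, dp)
  got <- read_community(rp, dp, sampling_years = design$sampling_years,
                        missing_years = design$missing_years)
  cm <- got$community
  # spruce sampled in its exposure calendar year -> year 0
  expect_equal(cm$exposure_year[cm$log_id == "L1"], 0)
  # beech exposed the previous autumn -> first sampled year is year 1
  expect_equal(cm$exposure_year[cm$log_id == "L2" & cm$species_id == "sA"], 1)
  # duplicate (log, year, species) rows are summed
  expect_equal(cm$count[cm$log_id == "L2" & cm$species_id == "sB"], 5)
  expect_equal(nrow(cm), 4)
})

test_that("reader drops zeros, rejects bad logs, flags unsampled years", {
  design <- toy_design()
  dp <- withr::local_tempfile(fileext = ".csv")
  write_design(design, dp)
  write_rec <- function(rec) {
    rp <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    write.csv(rec, rp, row.names = FALSE)
    rp
  }
  rp0 <- write_rec(data.frame(log_id = "L1", calendar_year = 2014,
                              species_id = c("sA", "sB"), count = c(0, 2)))
  got <- read_community(rp0, dp, design$sampling_years, design$missing_years)
  expect_equal(nrow(got$community), 1)

  rp1 <- write_rec(data.frame(log_id = "nope", calendar_year = 2014,
                              species_id = "sA", count = 1))
  expect_error(read_community(rp1, dp, design$sampling_years),
               "unknown log_id")

  rp2 <- write_rec(data.frame(log_id = "L2", calendar_year = 2014,
                              species_id = "sA", count = -2))
  expect_error(read_community(rp2, dp, design$sampling_years), "egative")

  rp3 <- write_rec(data.frame(log_id = "L2", calendar_year = c(2014, 2020),
                              species_id = "sA", count = 2))
  expect_warning(
    got3 <- read_community(rp3, dp, design$sampling_years,
                           design$missing_years),
    "unsampled year")
  expect_equal(nrow(got3$community), 2)  # flagged but kept
})

test_that("community write/read round trip is the identity on records", {
  design <- toy_design()
  cm <- toy_community(design)
  rp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_community(cm, design, rp)
  write_design(design, dp)
  back <- read_community(rp, dp, design$sampling_years,
                         design$missing_years)$community
  expect_equal(as.data.frame(back), as.data.frame(cm))
})

test_that("overlap summary matches hand-enumerated Venn counts", {
  # memberships: sA {spruce,beech}, sB {spruce,fir}, sC {beech,fir},
  # sD {beech}, sE {fir}
  cm <- toy_community()
  ov <- summarize_overlap(cm)
  per <- setNames(ov$per_species$n_species, ov$per_species$tree_species)
  expect_equal(per[["spruce"]], 2)
  expect_equal(per[["beech"]], 3)
  expect_equal(per[["fir"]], 3)
  expect_equal(ov$shared_pairs[["beech-fir"]], 1)   # sC
  expect_equal(ov$shared_pairs[["beech-spruce"]], 1) # sA
  expect_equal(ov$shared_pairs[["fir-spruce"]], 1)  # sB
  expect_equal(ov$shared_all, 0)
  expect_equal(ov$total_individuals, sum(cm$count))
  expect_equal(ov$total_species, 5)
  # Venn monotonicity
  expect_true(all(ov$shared_all <= ov$shared_pairs))
  expect_true(all(ov$shared_pairs <= max(per)))
})

test_that("overlap degenerate cases: identical and disjoint pools", {
  design <- toy_design()
  same <- community_table(
    expand.grid(log_id = c("L1", "L2", "L3"), exposure_year = 1,
                species_id = c("x", "y"), count = 1,
                stringsAsFactors = FALSE), design)
  ov <- summarize_overlap(same)
  expect_true(all(ov$shared_pairs == 2) && ov$shared_all == 2)

  disj <- community_table(
    data.frame(log_id = c("L1", "L2", "L3"), exposure_year = 1,
               species_id = c("x", "y", "z"), count = 1), design)
  ov2 <- summarize_overlap(disj)
  expect_true(all(ov2$shared_pairs == 0) && ov2$shared_all == 0)
})

test_that("assemblage matrix applies species filter and exclusions", {
  design <- toy_design()
  cm <- toy_community(design)
  m0 <- assemblage_matrix(cm, design, min_species = 0)
  expect_equal(nrow(m0),
               nrow(unique(cm[c("log_id", "exposure_year")])))
  expect_equal(sum(m0), sum(cm$count))
  # (L3, year 1) has 2 species; a 4-species filter drops everything here
  m2 <- assemblage_matrix(cm, design, min_species = 2)
  expect_true(all(rowSums(m2 > 0) >= 2))
  expect_true("L3|1" %in% rownames(m2))
  suppressWarnings(m4 <- assemblage_matrix(cm, design, min_species = 4))
  expect_equal(nrow(m4), 0)
  # exclusion removes the spruce year-0 assemblage
  mx <- assemblage_matrix(cm, design, min_species = 0,
                          exclusions = data.frame(tree_species = "spruce",
                                                  exposure_year = 0))
  expect_false("L1|0" %in% rownames(mx))
  expect_true("L1|1" %in% rownames(mx))
  # monotone: raising min_species never adds rows
  rows <- vapply(0:3, function(k) {
    suppressWarnings(nrow(assemblage_matrix(cm, design, min_species = k)))
  }, numeric(1))
  expect_true(all(diff(rows) <= 0))
})

test_that("trend data covers sampled log-years with genuine zeros", {
  design <- toy_design()
  cm <- toy_community(design)
  td <- trend_data(cm, design)
  # L1 (spruce): years 0..6, 8..11 (2020 absent); L2/L3: 1..7, 9..12
  expect_equal(sum(td$log_id == "L1"), 11)
  expect_false(7 %in% td$exposure_year[td$log_id == "L1"])
  expect_false(8 %in% td$exposure_year[td$log_id == "L2"])
  expect_equal(sum(td$abundance), sum(cm$count))
  expect_true(all(td$abundance[td$exposure_year > 3] == 0))
  expect_equal(sum(td$n_species > 0), nrow(unique(cm[c("log_id",
                                                       "exposure_year")])))
})
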