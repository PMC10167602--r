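test_that("wide cohort tables read back directly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 2),
    timepoint = rep(c("baseline", "followup"), 2),
    years_from_baseline = c(0, 1.8, 0, 2.1),
    group = "CU", abeta = "positive",
    R01 = c(1.2, 1.3, 1.1, 1.15), R02 = c(1.4, 1.5, 1.3, 1.35),
    check.names = FALSE)
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  cohort <- read_cohort(tmp)
  expect_equal(nrow(cohort$subjects), 2)
  expect_equal(cohort$subjects$interval_years, c(1.8, 2.1))
  expect_equal(cohort$baseline["s1", "R01"], 1.2)
  expect_equal(cohort$followup["s2", "R02"], 1.35)
})

test_that("subjects missing a timepoint are dropped and logged", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    subject_id = c("s1", "s1", "s2"),
    timepoint = c("baseline", "followup", "baseline"),
    years_from_baseline = c(0, 1.8, 0),
    group = "CU", abeta = "positive", R01 = c(1.2, 1.3, 1.1))
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(cohort <- read_cohort(tmp), "dropped 1 subject")
  expect_equal(cohort$subjects$subject_id, "s1")
  expect_equal(cohort$dropped$subject_id, "s2")
})

test_that("malformed headers and nonpositive SUVR are rejected with names", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(subject_id = "s1", timepoint = "baseline",
                    group = "CU", abeta = "positive", R01 = 1.2)
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "years_from_baseline")

  tab2 <- data.frame(
    subject_id = c("s1", "s1"), timepoint = c("baseline", "followup"),
    years_from_baseline = c(0, 1.8), group = "CU", abeta = "positive",
    R01 = c(-1.2, 1.3))
  write.table(tab2, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tmp), "s1.*R01")
})

test_that("write/read round-trips are lossless in both dialects", {
  gen <- small_sim(seed = 3)
  for (dialect in c("wide", "long")) {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_cohort(gen$cohort, tmp, dialect = dialect)
    back <- read_cohort(tmp, dialect = dialect,
                        catalog = gen$cohort$catalog)
    expect_equal(back$baseline, gen$cohort$baseline, tolerance = 1e-12)
    expect_equal(back$followup, gen$cohort$followup, tolerance = 1e-12)
    expect_equal(back$subjects, gen$cohort$subjects, tolerance = 1e-12)
  }
})

test_that("region set JSON round-trips and validates stage indices", {
  cat <- tiny_catalog(6)
  sets <- validate_region_sets(list(
    region_set("DDS_1", c("R01", "R02"), 1),
    region_set("DDS_2", c("R03", "R04"), 2),
    region_set("meta", c("R01", "R03", "R05"))), cat)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_region_sets(sets, tmp)
  back <- read_region_sets(tmp, catalog = cat)
  expect_equal(back, sets)
  expect_error(
    validate_region_sets(list(region_set("DDS_2", "R01", 2)), cat),
    "consecutive")
  expect_error(
    validate_region_sets(list(region_set("x", "nope")), cat), "unknown")
})

test_that("connectivity reader validates symmetry and reorders to catalog", {
  m <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3,
              dimnames = list(c("R02", "R01", "R03"),
                              c("R02", "R01", "R03")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(connectivity_matrix(m), tmp)
  cat3 <- region_catalog(c("R01", "R02", "R03"), volume = rep(1, 3))
  conn <- read_connectivity(tmp, catalog = cat3)
  expect_equal(rownames(conn), c("R01", "R02", "R03"))
  # permutation oracle: values preserved under reordering
  expect_equal(conn["R01", "R03"], m["R01", "R03"])
  expect_equal(conn["R02", "R03"], m["R02", "R03"])
  expect_equal(diag(unclass(conn)), setNames(rep(1, 3), rownames(conn)))

  bad <- m
  bad["R01", "R03"] <- bad["R01", "R03"] + 0.2
  expect_error(connectivity_matrix(bad), "asymmetric")
})

test_that("reference normalization uses volume-weighted means and is
           scale-invariant", {
  cat2 <- region_catalog(c("ref1", "ref2", "target"),
                         volume = c(100, 300, 500))
  uptake <- c(ref1 = 1.0, ref2 = 2.0, target = 3.5)
  suvr <- normalize_to_reference(uptake, c("ref1", "ref2"), cat2)
  # weighted reference mean (100*1 + 300*2)/400 = 1.75
  expect_equal(unname(suvr["target"]), 3.5 / 1.75)

  flat <- normalize_to_reference(c(ref1 = 2, ref2 = 2, target = 2),
                                 c("ref1", "ref2"), cat2)
  expect_equal(unname(flat), rep(1, 3))

  expect_equal(unname(normalize_to_reference(
    c(ref1 = 1.25, target = 2, ref2 = 1.25), "ref1", cat2)["target"]), 1.6)

  scaled <- normalize_to_reference(uptake * 7.3, c("ref1", "ref2"), cat2)
  expect_equal(scaled, suvr, tolerance = 1e-12)

  expect_error(normalize_to_reference(uptake, character(0), cat2), "empty")
})
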