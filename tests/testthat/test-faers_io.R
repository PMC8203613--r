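write_fixture_files <- function(raw, dir, dialect = "dollar") {
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"),
             outc = file.path(dir, "outc.txt"))
  for (nm in names(paths)) {
    if (dialect == "dollar") {
      write.table(raw[[nm]], paths[[nm]], sep = "$", quote = FALSE,
                  row.names = FALSE, na = "")
    } else {
      write.csv(raw[[nm]], paths[[nm]], row.names = FALSE, na = "")
    }
  }
  paths
}

test_that("both dialects read identically and preserve role codes", {
  raw <- five_report_raw()
  for (dialect in c("dollar", "comma")) {
    dir <- withr::local_tempdir()
    p <- write_fixture_files(raw, dir, dialect)
    tabs <- read_faers_tables(p["demo"], p["drug"], p["reac"], p["outc"],
                              dialect = dialect)
    expect_equal(nrow(tabs$demo), 5L)
    expect_equal(tabs$drug$role_cod, raw$drug$role_cod)
    expect_equal(unname(tabs$skipped), rep(0L, 4))
  }
})

test_that("missing required columns raise a schema error naming them", {
  raw <- five_report_raw()
  raw$drug$role_cod <- NULL
  dir <- withr::local_tempdir()
  p <- write_fixture_files(raw, dir)
  expect_error(
    read_faers_tables(p["demo"], p["drug"], p["reac"], p["outc"]),
    "role_cod")
  expect_error(
    read_faers_tables(p["demo"], p["drug"], p["reac"], p["outc"]),
    "drug")
})

test_that("malformed rows are skipped and counted, not fatal", {
  raw <- five_report_raw()
  dir <- withr::local_tempdir()
  p <- write_fixture_files(raw, dir)
  cat("6$E4$stray$fields\n", file = p["reac"], append = TRUE)
  tabs <- read_faers_tables(p["demo"], p["drug"], p["reac"], p["outc"])
  expect_equal(unname(tabs$skipped["reac"]), 1L)
  expect_equal(nrow(tabs$reac), 7L)
})

test_that("age unit conversion follows the FAERS code table", {
  expect_equal(age_to_years(6, "MON"), 0.5)
  expect_equal(age_to_years(5, "DEC"), 50)
  expect_equal(age_to_years(40, "YR"), 40)
  expect_equal(age_to_years(52, "WK"), 1)
  expect_equal(age_to_years(365, "DY"), 1)
  expect_equal(age_to_years(8760, "HR"), 1)
  expect_true(is.na(age_to_years("n/a", "YR")))
  expect_true(is.na(age_to_years(-3, "YR")))  # negative ages are nonsense
})

test_that("assembly collapses PT sets, drops empty reports, counts orphans", {
  raw <- list(
    demo = data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                      fda_dt = "20150101", sex = "M", age = "40",
                      age_cod = "YR"),
    drug = data.frame(primaryid = c("1", "9"), drugname = c("D", "D"),
                      role_cod = "PS"),
    reac = data.frame(primaryid = c("1", "1", "9"), pt = c("E1", "E1", "E2")),
    outc = data.frame(primaryid = "1", outc_cod = "HO"))
  rs <- assemble_reports(raw)
  expect_equal(n_reports(rs), 1L)  # report 2 has no reactions
  expect_equal(rs$reactions$pt, "E1")
  cnt <- rs$counters
  expect_equal(unname(cnt["reac_collapsed"]), 1L)
  expect_equal(unname(cnt["reac_orphans"]), 1L)
  expect_equal(unname(cnt["drug_orphans"]), 1L)
  expect_equal(unname(cnt["reports_dropped_no_reactions"]), 1L)
  # conservation: kept pairs + collapsed + orphans = input reaction rows
  expect_equal(nrow(rs$reactions) + cnt[["reac_collapsed"]] +
                 cnt[["reac_orphans"]], nrow(raw$reac))
})

test_that("assembly conserves reaction rows on random fixtures", {
  set.seed(404)
  for (rep in 1:10) {
    raw <- random_raw(sample(5:40, 1))
    rs <- assemble_reports(raw)
    cnt <- rs$counters
    expect_equal(nrow(rs$reactions) + cnt[["reac_collapsed"]] +
                   cnt[["reac_orphans"]], nrow(raw$reac))
  }
})

test_that("deduplication keeps the latest FDA date per case", {
  raw <- list(
    demo = data.frame(primaryid = c("10", "11"), caseid = c("77", "77"),
                      fda_dt = c("20190101", "20190301"), sex = "M",
                      age = "40", age_cod = "YR"),
    drug = data.frame(primaryid = c("10", "11"), drugname = "D",
                      role_cod = "PS"),
    reac = data.frame(primaryid = c("10", "11"), pt = "E1"),
    outc = data.frame(primaryid = character(0), outc_cod = character(0)))
  rs <- deduplicate(assemble_reports(raw))
  expect_equal(rs$demo$primary_id, "11")
  expect_equal(rs$demo$fda_date, 20190301L)
})

test_that("deduplication breaks FDA-date ties by the largest primary id", {
  raw <- list(
    demo = data.frame(primaryid = c("5", "12"), caseid = c("9", "9"),
                      fda_dt = "20190101", sex = "M", age = "40",
                      age_cod = "YR"),
    drug = data.frame(primaryid = c("5", "12"), drugname = "D",
                      role_cod = "PS"),
    reac = data.frame(primaryid = c("5", "12"), pt = "E1"),
    outc = data.frame(primaryid = character(0), outc_cod = character(0)))
  rs <- deduplicate(assemble_reports(raw))
  expect_equal(rs$demo$primary_id, "12")  # numeric, not lexicographic, order
})

test_that("deduplication is idempotent and preserves the case-id set", {
  set.seed(99)
  for (rep in 1:10) {
    rs <- assemble_reports(random_raw(sample(6:40, 1)))
    d1 <- deduplicate(rs)
    d2 <- deduplicate(d1)
    expect_identical(d1$demo, d2$demo)
    expect_lte(n_reports(d1), n_reports(rs))
    expect_setequal(unique(d1$demo$case_id), unique(rs$demo$case_id))
    expect_false(anyDuplicated(d1$demo$case_id) > 0)
    # survivor has the maximal date within its case (brute force)
    for (cid in unique(rs$demo$case_id)) {
      kept <- d1$demo$fda_date[d1$demo$case_id == cid]
      expect_equal(kept, max(rs$demo$fda_date[rs$demo$case_id == cid]))
    }
  }
})

test_that("suspect filter requires a PS/SS role for the query drug", {
  rs <- five_report_set()
  kept <- filter_suspect(rs, "D")
  expect_setequal(kept$demo$primary_id, c("1", "2"))  # R5 is concomitant-only
  expect_equal(n_reports(filter_suspect(rs, drug_query("d"))), 2L)  # casefold
  expect_error(drug_query(character(0)), "non-empty")
})

test_that("completeness filter counts missing items against the threshold", {
  raw <- list(
    demo = data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                      fda_dt = "20150101",
                      sex = c("", "M"), age = c("", "40"),
                      age_cod = "YR", occp_cod = c("", "MD")),
    drug = data.frame(primaryid = c("1", "2"), drugname = "D",
                      role_cod = "PS"),
    reac = data.frame(primaryid = c("1", "2"), pt = "E1"),
    outc = data.frame(primaryid = "2", outc_cod = "HO"))
  rs <- assemble_reports(raw)
  # report 1 misses sex, age, reporter, outcomes = 4 items
  expect_equal(filter_completeness(rs, 3)$demo$primary_id, "2")
  expect_equal(n_reports(filter_completeness(rs, 4)), 2L)
  expect_equal(n_reports(filter_completeness(rs, 0)), 1L)  # complete one kept
})

test_that("completeness survivors match a brute-force count", {
  set.seed(2718)
  for (rep in 1:5) {
    rs <- assemble_reports(random_raw(10))
    miss <- (is.na(rs$demo$sex) | rs$demo$sex == "unknown") +
      is.na(rs$demo$age_years) +
      (rs$demo$reporter == "unknown") +
      is.na(rs$demo$fda_date) +
      !(rs$demo$primary_id %in% rs$outcomes$primary_id)
    for (k in 0:4) {
      expect_equal(n_reports(filter_completeness(rs, k)), sum(miss <= k))
    }
  }
})

test_that("period filter is closed on both ends and validates bounds", {
  rs <- five_report_set()  # all fda_dt 20150301
  expect_equal(n_reports(filter_period(rs, 20150301, 20150301)), 5L)
  expect_equal(n_reports(filter_period(rs, 20150302, 20191231)), 0L)
  expect_equal(n_reports(filter_period(rs, 20060701, 20150228)), 0L)
  expect_error(filter_period(rs, 20200101, 20191231), "exceed")
  expect_error(filter_period(rs, 20069999, 20191231), "valid")
})

test_that("row filters commute", {
  set.seed(31)
  for (rep in 1:5) {
    rs <- deduplicate(assemble_reports(random_raw(30)))
    ab <- filter_period(filter_completeness(rs, 2), 20120101, 20161231)
    ba <- filter_completeness(filter_period(rs, 20120101, 20161231), 2)
    expect_setequal(ab$demo$primary_id, ba$demo$primary_id)
    ac <- filter_suspect(filter_completeness(rs, 2), "D")
    ca <- filter_completeness(filter_suspect(rs, "D"), 2)
    expect_setequal(ac$demo$primary_id, ca$demo$primary_id)
  }
})

test_that("a report set round-trips through the normalised writer", {
  rs <- five_report_set()
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_set(rs, path)
  back <- read.csv(path, colClasses = "character")
  expect_equal(nrow(back), 5L)
  expect_true(file.exists(paste0(path, ".provenance.json")))
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  steps <- vapply(prov$provenance, `[[`, "", "step")
  expect_equal(steps, c("assemble", "deduplicate"))
  expect_equal(back$reactions[back$primary_id == "1"], "E1;E2")
})
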