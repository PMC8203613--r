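test_that("generation is fully reproducible from the seed", {
  cfg <- simulation_config(300, seed = 17)
  s1 <- generate_reports(cfg)
  s2 <- generate_reports(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$reports$demo, s2$reports$demo)
  # a different seed changes the draw
  s3 <- generate_reports(simulation_config(300, seed = 18))
  expect_false(identical(s1$tables$reac, s3$tables$reac))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(simulation_config(0), "count")
  expect_error(simulation_config(10, mean_events_per_report = 0.5), "lie in")
  expect_error(simulation_config(10, duplicate_rate = 1.5), "rates")
  expect_error(
    simulation_config(10, associations = data.frame(drug = "nope",
                                                    pt = "Nausea", rr = 2)),
    "unknown association drug")
  expect_error(
    simulation_config(10, associations = data.frame(drug = "drug_a",
                                                    pt = "nope", rr = 2)),
    "unknown association PT")
  expect_error(
    simulation_config(10, associations = data.frame(drug = "drug_a",
                                                    pt = "Nausea", rr = 0)),
    "> 0")
})

test_that("emitted duplicates match the binomial expectation and dedup", {
  n <- 10000
  cfg <- simulation_config(n, duplicate_rate = 0.1, seed = 23)
  sim <- generate_reports(cfg)
  n_dup <- sim$truth$n_duplicates
  # within 3 sigma of Binomial(n, 0.1)
  expect_lt(abs(n_dup - n * 0.1), 3 * sqrt(n * 0.1 * 0.9))
  expect_equal(n_reports(sim$reports), n + n_dup)
  rs <- deduplicate(sim$reports)
  # dedup removes exactly the emitted duplicate versions
  expect_equal(n_reports(rs), n)
  expect_equal(unname(rs$counters["dedup_removed"]), n_dup)
  # the survivor of a duplicated case is the later version
  expect_false(anyDuplicated(rs$demo$case_id) > 0)
})

test_that("generated sets satisfy the assembly invariants", {
  cfg <- simulation_config(2000, seed = 29)
  rs <- generate_reports(cfg)$reports
  expect_false(anyDuplicated(rs$demo$primary_id) > 0)
  expect_true(all(rs$demo$primary_id %in% rs$reactions$primary_id))
  expect_true(all(table(rs$drugs$primary_id) >= 1))
  # every report has a PS drug
  ps <- rs$drugs$primary_id[rs$drugs$role == "PS"]
  expect_setequal(unique(ps), rs$demo$primary_id)
  # age groups are a pure function of age
  expect_equal(rs$demo$age_group,
               pvsignal:::age_group_of(rs$demo$age_years))
})

test_that("the event-count model hits the configured mean", {
  cfg <- simulation_config(50000, seed = 37)
  rs <- deduplicate(generate_reports(cfg)$reports)
  m <- nrow(rs$reactions) / n_reports(rs)
  expect_gte(m, 2.45)
  expect_lte(m, 2.61)
})

test_that("missingness rates are honoured", {
  cfg <- simulation_config(20000, seed = 41,
                           missingness = c(sex = 0.3, age = 0.5,
                                           reporter = 0.1))
  rs <- generate_reports(cfg)$reports
  expect_lt(abs(mean(rs$demo$sex == "unknown") - 0.3), 0.02)
  expect_lt(abs(mean(is.na(rs$demo$age_years)) - 0.5), 0.02)
  expect_lt(abs(mean(rs$demo$reporter == "unknown") - 0.1), 0.02)
})

test_that("simulated tables round-trip through the file readers", {
  cfg <- simulation_config(200, seed = 53)
  sim <- generate_reports(cfg)
  for (dialect in c("dollar", "comma")) {
    dir <- withr::local_tempdir()
    write_faers_tables(sim, dir, dialect = dialect)
    tabs <- read_faers_tables(file.path(dir, "demo.txt"),
                              file.path(dir, "drug.txt"),
                              file.path(dir, "reac.txt"),
                              file.path(dir, "outc.txt"),
                              dialect = dialect)
    back <- assemble_reports(tabs)
    expect_equal(back$demo, sim$reports$demo)
    expect_equal(back$reactions, sim$reports$reactions)
    expect_equal(back$drugs, sim$reports$drugs)
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
    expect_equal(truth$seed, 53L)
  }
})

test_that("the closed-form expected table recovers the null and the RR", {
  # null: expected ROR is exactly 1
  cfg0 <- simulation_config(10000, seed = 1)
  et0 <- expected_table(cfg0, "drug_a", "Nausea")
  expect_equal(ror(et0)$ror, 1.0, tolerance = 1e-9)
  # linearity: doubling n_reports doubles every cell
  cfg2 <- simulation_config(20000, seed = 1)
  et2 <- expected_table(cfg2, "drug_a", "Nausea")
  expect_equal(c(et2$a, et2$b, et2$c, et2$d) /
                 c(et0$a, et0$b, et0$c, et0$d), rep(2, 4))
  # rare drug, rare event, RR 4: expected ROR close to the injected RR
  pts <- data.frame(pt = sprintf("pt_%03d", 1:50),
                    weight = c(0.002, rep(0.998 / 49, 49)))
  drugs <- data.frame(name = c("darunavir", "drug_b", "drug_c", "drug_d"),
                      p_suspect = c(0.01, 0.3, 0.1, 0.05))
  cfg <- simulation_config(200000, drugs = drugs, pts = pts,
                           associations = data.frame(drug = "darunavir",
                                                     pt = "pt_001", rr = 4),
                           seed = 1)
  er <- ror(expected_table(cfg, "darunavir", "pt_001"))$ror
  expect_gte(er, 3.8)
  expect_lte(er, 4.2)
  expect_error(expected_table(cfg, "ghost", "pt_001"), "unknown drug")
  expect_error(expected_table(cfg, "darunavir", "ghost"), "unknown PT")
})

test_that("a capped per-report probability warns", {
  pts <- data.frame(pt = c("common", "other"), weight = c(0.9, 0.1))
  drugs <- data.frame(name = "drug_a", p_suspect = 0.5)
  cfg <- simulation_config(50, drugs = drugs, pts = pts,
                           mean_events_per_report = 1.5,
                           associations = data.frame(drug = "drug_a",
                                                     pt = "common", rr = 50),
                           seed = 2)
  expect_warning(generate_reports(cfg), "capped")
})

test_that("recovery statistics are deterministic for a fixed seed", {
  pts <- data.frame(pt = sprintf("pt_%02d", 1:20), weight = 1 / 20)
  drugs <- data.frame(name = c("drug_a", "drug_b"),
                      p_suspect = c(0.1, 0.2))
  cfg <- simulation_config(4000, drugs = drugs, pts = pts,
                           associations = data.frame(drug = "drug_a",
                                                     pt = "pt_01", rr = 6),
                           seed = 71)
  r1 <- recovery_experiment(cfg, replicates = 1)
  r2 <- recovery_experiment(cfg, replicates = 1)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_true(is.finite(r1$mean_ror))
})

test_that("the ROR estimate concentrates on the truth as n grows", {
  pts <- data.frame(pt = sprintf("pt_%02d", 1:25),
                    weight = c(0.004, rep(0.996 / 24, 24)))
  drugs <- data.frame(name = c("drug_a", "drug_b", "drug_c"),
                      p_suspect = c(0.05, 0.3, 0.1))
  assoc <- data.frame(drug = "drug_a", pt = "pt_01", rr = 4)
  rmse <- vapply(c(5000, 20000, 80000), function(n) {
    cfg <- simulation_config(n, drugs = drugs, pts = pts,
                             associations = assoc, seed = 1000 + n)
    target <- log(ror(expected_table(cfg, "drug_a", "pt_01"))$ror)
    rec <- recovery_experiment(cfg, replicates = 10)
    sqrt(mean((log(rec$per_replicate$ror) - target)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
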