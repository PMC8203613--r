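# Fixtures and independent oracles shared across test files. All fixtures
# are built in code; nothing binary ships with the tests.

norm_term <- pvsignal:::norm_term

# The canonical five-report fixture: drug D suspect in R1 (PS) and R2 (SS),
# concomitant-only in R5; drug X elsewhere.
#   R1 = D(PS): {E1, E2};  R2 = D(SS): {E1};  R3 = X(PS): {E1};
#   R4 = X(PS): {E2, E3};  R5 = D(C) + X(PS): {E1}
five_report_raw <- function() {
  list(
    demo = data.frame(
      primaryid = as.character(1:5), caseid = as.character(101:105),
      fda_dt = "20150301", sex = c("M", "F", "M", "F", "M"),
      age = c("40", "52", "31", "67", "45"), age_cod = "YR",
      occp_cod = c("MD", "PH", "CN", "MD", "OT"),
      stringsAsFactors = FALSE),
    drug = data.frame(
      primaryid = c("1", "2", "3", "4", "5", "5"),
      drugname = c("D", "D", "X", "X", "D", "X"),
      role_cod = c("PS", "SS", "PS", "PS", "C", "PS"),
      stringsAsFactors = FALSE),
    reac = data.frame(
      primaryid = c("1", "1", "2", "3", "4", "4", "5"),
      pt = c("E1", "E2", "E1", "E1", "E2", "E3", "E1"),
      stringsAsFactors = FALSE),
    outc = data.frame(
      primaryid = c("1", "3", "4"), outc_cod = c("HO", "OT", "DE"),
      stringsAsFactors = FALSE))
}

five_report_set <- function() deduplicate(assemble_reports(five_report_raw()))

small_dict <- function() {
  term_dictionary(
    data.frame(pt = c("E1", "E2", "E3", "Hepatocellular injury"),
               soc = c("SOC one", "SOC one", "SOC two",
                       "Hepatobiliary disorders")),
    smq_narrow = list(`SMQ alpha` = c("E1", "E3")),
    version_tag = "test")
}

# A random relational fixture for property tests; every report has >= 1
# reaction, case ids may repeat across versions.
random_raw <- function(n_reports, n_cases = max(2L, n_reports %/% 2L),
                       drugs = c("D", "X", "Z"), pts = paste0("E", 1:6)) {
  pid <- as.character(seq_len(n_reports))
  demo <- data.frame(
    primaryid = pid,
    caseid = as.character(sample.int(n_cases, n_reports, replace = TRUE)),
    fda_dt = format(as.Date("2010-01-01") +
                      sample.int(3000, n_reports, replace = TRUE), "%Y%m%d"),
    sex = sample(c("M", "F", ""), n_reports, replace = TRUE),
    age = as.character(sample(c(NA, 5:80), n_reports, replace = TRUE)),
    age_cod = "YR",
    occp_cod = sample(c("MD", "CN", ""), n_reports, replace = TRUE),
    stringsAsFactors = FALSE)
  n_drug <- n_reports + sample.int(n_reports, 1L)
  drug <- data.frame(
    primaryid = c(pid, sample(pid, n_drug - n_reports, replace = TRUE)),
    drugname = sample(drugs, n_drug, replace = TRUE),
    role_cod = sample(c("PS", "SS", "C", "I"), n_drug, replace = TRUE),
    stringsAsFactors = FALSE)
  n_reac <- n_reports + sample.int(2L * n_reports, 1L)
  reac <- data.frame(
    primaryid = c(pid, sample(pid, n_reac - n_reports, replace = TRUE)),
    pt = sample(pts, n_reac, replace = TRUE),
    stringsAsFactors = FALSE)
  outc <- data.frame(
    primaryid = sample(pid, n_reports %/% 2L),
    outc_cod = sample(c("DE", "LT", "HO", "DS", "OT"), n_reports %/% 2L,
                      replace = TRUE),
    stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac, outc = outc)
}

# Independent single-table oracle for the three statistics, written directly
# from the closed forms (plain scalar arithmetic, no shared code with the
# package internals).
oracle_stats <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  N <- a + b + c + d
  lror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- unname(suppressWarnings(
    stats::chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE))$statistic)
  point_ic <- (log(a) + log(N) - log(a + b) - log(a + c)) / log(2)
  g <- (N + 2) * (N + 2) / ((a + b + 1) * (a + c + 1))
  ic <- (log(a + 1) + log(N + 2) + log(N + 2) -
           log(N + g) - log(a + b + 1) - log(a + c + 1)) / log(2)
  v <- ((N - a + g - 1) / ((a + 1) * (1 + N + g)) +
          (N - a - b + 1) / ((a + b + 1) * (1 + N + 2)) +
          (N - a - c + 1) / ((a + c + 1) * (1 + N + 2))) / log(2)^2
  list(ror = exp(lror), ci_low = exp(lror - 1.96 * se),
       ci_high = exp(lror + 1.96 * se), prr = prr, chi2 = chi2,
       point_ic = point_ic, ic = ic, ic_sd = sqrt(v),
       ic_minus_2sd = ic - 2 * sqrt(v))
}

random_cells <- function() {
  # positive-cell tables spanning several magnitudes
  c(a = sample(1:80, 1), b = sample(1:400, 1),
    c = sample(1:400, 1), d = sample(10:5000, 1))
}

# Raw tables whose marginal counts equal the published descriptive table of
# the darunavir report series: 10,756 deduplicated reports, 27,234 reaction
# pairs, and the printed sex / age / reporter / outcome margins.
table1_raw <- function() {
  n <- 10756L
  pid <- as.character(seq_len(n))
  demo <- data.frame(
    primaryid = pid, caseid = pid, fda_dt = "20120601",
    sex = c(rep("M", 5859), rep("F", 3111), rep("", 1786)),
    age = c(rep("10", 477), rep("30", 2490), rep("50", 2814),
            rep("70", 342), rep("80", 101), rep("", 4532)),
    age_cod = "YR",
    occp_cod = c(rep("MD", 3950), rep("PH", 1022), rep("OT", 3628),
                 rep("LW", 18), rep("CN", 1836), rep("", 302)),
    stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = pid, drugname = "darunavir",
                     role_cod = "PS", stringsAsFactors = FALSE)
  # 2 distinct PTs per report, a 3rd for the first 5722: 27,234 pairs total
  i <- seq_len(n)
  reac <- data.frame(
    primaryid = c(pid, pid, pid[1:5722]),
    pt = c(sprintf("pt%03d", i %% 300L),
           sprintf("pt%03d", (i + 1L) %% 300L),
           sprintf("pt%03d", (i[1:5722] + 2L) %% 300L)),
    stringsAsFactors = FALSE)
  outc <- data.frame(
    primaryid = pid[1:4460],
    outc_cod = c(rep("DE", 102), rep("LT", 526), rep("HO", 3503),
                 rep("DS", 329)),
    stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac, outc = outc)
}
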