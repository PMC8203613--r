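#' Describe a drug-name query
#'
#' A drug query is a set of name patterns matched case-insensitively against
#' the free-text `drugname` field, either as exact matches on the
#' whitespace-normalised name (default) or as substring matches. FAERS drug
#' names are verbatim reporter text, so normalisation (trimming, whitespace
#' collapsing, casefolding) is always applied before comparison.
#'
#' @param patterns character vector of one or more drug-name patterns.
#' @param mode `"exact"` for whole-name matching after normalisation, or
#'   `"substring"` to match patterns anywhere within the normalised name.
#' @return An object of class `drug_query`.
#' @examples
#' drug_query(c("darunavir", "darunavir/ritonavir"))
#' @export
drug_query <- function(patterns, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  patterns <- patterns[!is.na(patterns)]
  patterns <- patterns[nzchar(trimws(patterns))]
  if (length(patterns) == 0L) {
    stop2("drug_query: 'patterns' must contain at least one non-empty name")
  }
  structure(list(patterns = norm_term(patterns), mode = mode,
                 raw = patterns),
            class = "drug_query")
}

as_drug_query <- function(x) {
  if (inherits(x, "drug_query")) return(x)
  if (is.character(x)) return(drug_query(x))
  stop2("expected a drug_query object or a character vector of drug names")
}

#' @export
print.drug_query <- function(x, ...) {
  cat("<drug_query> mode =", x$mode, "\n  patterns:",
      paste(x$raw, collapse = "; "), "\n")
  invisible(x)
}

# Does each normalised drug name match the query?
match_drug_names <- function(names_norm, query) {
  if (query$mode == "exact") {
    names_norm %in% query$patterns
  } else {
    hit <- rep(FALSE, length(names_norm))
    for (p in query$patterns) {
      hit <- hit | grepl(p, names_norm, fixed = TRUE)
    }
    hit
  }
}

# Required columns per table, in FAERS quarterly-ASCII naming.
.required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod"),
  drug = c("primaryid", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod")
)

# Robust delimited reader: rows whose field count disagrees with the header
# are skipped and counted rather than aborting the whole file.
.read_delim_robust <- function(path, sep, quote, encoding, label) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, encoding = encoding, warn = FALSE)
  if (length(lines) == 0L) stop2(label, " file is empty: ", path)
  nf <- utils::count.fields(textConnection(lines), sep = sep, quote = quote,
                            comment.char = "")
  nf[is.na(nf)] <- -1L
  good <- nf == nf[1]
  good[1] <- TRUE
  tab <- utils::read.table(text = lines[good], header = TRUE, sep = sep,
                           quote = quote, comment.char = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  names(tab) <- tolower(names(tab))
  attr(tab, "skipped") <- sum(!good)
  tab
}

#' Read FAERS-style relational tables
#'
#' Reads the four quarterly-ASCII style tables (demographics, drugs,
#' reactions, outcomes) as raw character tables. Two dialects are supported:
#' `"dollar"` (the `$`-delimited FAERS distribution format, no quoting) and
#' `"comma"` (CSV with quoting). Column names are matched case-insensitively;
#' extra columns are preserved but ignored downstream. Malformed rows are
#' skipped and counted, not fatal.
#'
#' @param demo_path,drug_path,reac_path,outc_path paths to the four tables.
#' @param dialect `"dollar"` or `"comma"`.
#' @param encoding file encoding; use `"latin1"` for legacy extracts.
#' @return A list of class `faers_tables` with elements `demo`, `drug`,
#'   `reac`, `outc` (character data frames) and `skipped`, a named count of
#'   malformed rows dropped per table.
#' @seealso [assemble_reports()]
#' @export
read_faers_tables <- function(demo_path, drug_path, reac_path, outc_path,
                              dialect = c("dollar", "comma"),
                              encoding = "UTF-8") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "dollar") "$" else ","
  quote <- if (dialect == "dollar") "" else "\""
  paths <- c(demo = unname(demo_path), drug = unname(drug_path),
             reac = unname(reac_path), outc = unname(outc_path))
  out <- list()
  skipped <- integer(0)
  for (nm in names(paths)) {
    tab <- .read_delim_robust(paths[[nm]], sep, quote, encoding, nm)
    missing_cols <- setdiff(.required_cols[[nm]], names(tab))
    if (length(missing_cols) > 0L) {
      stop2("schema error in ", nm, " file '", paths[[nm]],
            "': missing required column(s): ",
            paste(missing_cols, collapse = ", "))
    }
    skipped[nm] <- attr(tab, "skipped")
    attr(tab, "skipped") <- NULL
    out[[nm]] <- tab
  }
  out$skipped <- skipped
  class(out) <- "faers_tables"
  out
}

#' Convert a FAERS age value to years
#'
#' Applies the FAERS `age_cod` unit conventions: `DEC` decades, `YR` years,
#' `MON` months, `WK` weeks, `DY` days, `HR` hours. Unknown or missing codes
#' with a numeric age are treated as years.
#'
#' @param age numeric age values (or character, coerced).
#' @param age_cod unit codes, recycled against `age`.
#' @return numeric vector of ages in years (NA where unparseable).
#' @examples
#' age_to_years(6, "MON")   # 0.5
#' @export
age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(age_cod)))
  mult <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365,
            HR = 1 / 8760)
  m <- mult[unit]
  m[is.na(m)] <- 1
  out <- age * as.numeric(m)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

# Age bins used in descriptive tables.
age_group_of <- function(age_years) {
  g <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  a <- age_years[ok]
  g[ok] <- ifelse(a < 18, "<18",
           ifelse(a < 45, "18-44",
           ifelse(a < 65, "45-64",
           ifelse(a < 75, "65-74", ">=75"))))
  g
}

.sex_map <- c(M = "male", F = "female")
.reporter_map <- c(MD = "doctor", PH = "pharmacist", OT = "other-medical",
                   HP = "other-medical", LW = "lawyer", CN = "consumer")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.sae_codes <- c("DE", "LT", "HO", "DS")
.role_codes <- c("PS", "SS", "C", "I")

new_report_set <- function(demo, drugs, reactions, outcomes,
                           provenance = list(), counters = integer(0)) {
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, provenance = provenance,
                 counters = counters),
            class = "report_set")
}

add_provenance <- function(reports, step, params = list()) {
  reports$provenance[[length(reports$provenance) + 1L]] <-
    list(step = step, params = params)
  reports
}

has_provenance <- function(reports, step) {
  any(vapply(reports$provenance, function(p) identical(p$step, step),
             logical(1)))
}

#' Number of reports in a report set
#' @param reports a `report_set`.
#' @return integer count of reports.
#' @export
n_reports <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  nrow(reports$demo)
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set>", nrow(x$demo), "reports;",
      nrow(x$drugs), "drug rows;",
      nrow(x$reactions), "reaction (report, PT) pairs;",
      nrow(x$outcomes), "outcome rows\n")
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(vapply(x$provenance, `[[`, character(1), "step"),
              collapse = " -> "), "\n")
  }
  if (length(x$counters)) {
    cat("  counters:",
        paste(names(x$counters), x$counters, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Restrict the relational side tables to a set of surviving primary ids,
# preserving row order.
subset_report_set <- function(reports, keep_ids) {
  reports$demo <- reports$demo[reports$demo$primary_id %in% keep_ids, ,
                               drop = FALSE]
  rownames(reports$demo) <- NULL
  for (nm in c("drugs", "reactions", "outcomes")) {
    tab <- reports[[nm]]
    reports[[nm]] <- tab[tab$primary_id %in% keep_ids, , drop = FALSE]
    rownames(reports[[nm]]) <- NULL
  }
  reports
}

#' Assemble per-case safety reports from raw tables
#'
#' Builds a normalised `report_set` from the raw table bundle: one report per
#' `primaryid` present in the demographics table, with drugs, reactions and
#' outcomes attached by key. Reaction PTs are collapsed to set semantics
#' within a report (duplicates counted), reports without any reaction are
#' dropped (counted), and drug/reaction rows referencing an unknown
#' `primaryid` are excluded as orphans (counted). Ages are converted to years
#' via [age_to_years()] and binned; sex, reporter occupation, drug roles and
#' outcome codes are normalised to their controlled vocabularies.
#'
#' `raw` may also be a plain list with elements `demo`, `drug`, `reac`,
#' `outc` holding data frames in FAERS column naming, which makes it easy to
#' assemble in-memory fixtures.
#'
#' @param raw a `faers_tables` bundle from [read_faers_tables()], or a list
#'   of four compatible data frames.
#' @return A `report_set` with provenance step `"assemble"` and counters
#'   `reac_rows_in`, `reac_collapsed`, `reac_orphans`, `drug_orphans`,
#'   `outc_orphans`, `reports_dropped_no_reactions`, `invalid_fda_dt`.
#' @export
assemble_reports <- function(raw) {
  for (nm in c("demo", "drug", "reac", "outc")) {
    if (is.null(raw[[nm]])) stop2("assemble_reports: missing table '", nm, "'")
    missing_cols <- setdiff(.required_cols[[nm]], tolower(names(raw[[nm]])))
    if (length(missing_cols) > 0L) {
      stop2("schema error in ", nm, ": missing required column(s): ",
            paste(missing_cols, collapse = ", "))
    }
    names(raw[[nm]]) <- tolower(names(raw[[nm]]))
  }
  demo <- raw$demo

  pid <- trimws(as.character(demo$primaryid))
  if (anyDuplicated(pid)) {
    stop2("assemble_reports: duplicated primaryid in demo table")
  }
  fda_raw <- suppressWarnings(as.integer(trimws(as.character(demo$fda_dt))))
  fda_date <- date_to_ymd(ymd_to_date(fda_raw))  # validates the calendar date
  invalid_fda <- sum(!is.na(fda_raw) & is.na(fda_date)) + sum(is.na(fda_raw))

  sex_raw <- toupper(trimws(as.character(demo$sex)))
  sex <- unname(.sex_map[sex_raw])
  sex[is.na(sex)] <- "unknown"

  age_years <- age_to_years(demo$age, demo$age_cod)

  if ("occp_cod" %in% names(demo)) {
    rep_raw <- toupper(trimws(as.character(demo$occp_cod)))
    reporter <- unname(.reporter_map[rep_raw])
    reporter[is.na(reporter)] <- "unknown"
  } else {
    reporter <- rep("unknown", nrow(demo))
  }

  demo_out <- data.frame(
    primary_id = pid,
    case_id = trimws(as.character(demo$caseid)),
    fda_date = fda_date,
    sex = sex,
    age_years = age_years,
    age_group = age_group_of(age_years),
    reporter = reporter,
    stringsAsFactors = FALSE
  )
  if ("reporter_country" %in% names(demo)) {
    cc <- trimws(as.character(demo$reporter_country))
    cc[!nzchar(cc)] <- NA_character_
    demo_out$country <- cc
  }
  if ("wt" %in% names(demo)) {
    demo_out$weight <- suppressWarnings(as.numeric(demo$wt))
  }

  # Drugs
  dr <- raw$drug
  drugs <- data.frame(
    primary_id = trimws(as.character(dr$primaryid)),
    drug_name = trimws(as.character(dr$drugname)),
    role = toupper(trimws(as.character(dr$role_cod))),
    stringsAsFactors = FALSE
  )
  drugs <- drugs[nzchar(drugs$drug_name) & drugs$role %in% .role_codes, ,
                 drop = FALSE]
  drug_orphans <- sum(!(drugs$primary_id %in% pid))
  drugs <- drugs[drugs$primary_id %in% pid, , drop = FALSE]
  rownames(drugs) <- NULL

  # Reactions: set semantics within a report
  rc <- raw$reac
  reac <- data.frame(
    primary_id = trimws(as.character(rc$primaryid)),
    pt = trimws(as.character(rc$pt)),
    stringsAsFactors = FALSE
  )
  reac <- reac[nzchar(reac$pt), , drop = FALSE]
  reac_rows_in <- nrow(reac)
  reac_orphans <- sum(!(reac$primary_id %in% pid))
  reac <- reac[reac$primary_id %in% pid, , drop = FALSE]
  dup <- duplicated(paste(reac$primary_id, norm_term(reac$pt), sep = "\r"))
  reac_collapsed <- sum(dup)
  reac <- reac[!dup, , drop = FALSE]
  rownames(reac) <- NULL

  # Outcomes
  oc <- raw$outc
  outc <- data.frame(
    primary_id = trimws(as.character(oc$primaryid)),
    outc_cod = toupper(trimws(as.character(oc$outc_cod))),
    stringsAsFactors = FALSE
  )
  outc <- outc[outc$outc_cod %in% .outcome_codes, , drop = FALSE]
  outc_orphans <- sum(!(outc$primary_id %in% pid))
  outc <- outc[outc$primary_id %in% pid, , drop = FALSE]
  outc <- outc[!duplicated(paste(outc$primary_id, outc$outc_cod)), ,
               drop = FALSE]
  rownames(outc) <- NULL

  # Reports without any reaction carry no analysable event: drop them.
  has_reac <- demo_out$primary_id %in% reac$primary_id
  dropped_no_reac <- sum(!has_reac)
  demo_out <- demo_out[has_reac, , drop = FALSE]
  rownames(demo_out) <- NULL
  keep <- demo_out$primary_id
  drugs <- drugs[drugs$primary_id %in% keep, , drop = FALSE]
  outc <- outc[outc$primary_id %in% keep, , drop = FALSE]

  counters <- c(reac_rows_in = reac_rows_in,
                reac_collapsed = reac_collapsed,
                reac_orphans = reac_orphans,
                drug_orphans = drug_orphans,
                outc_orphans = outc_orphans,
                reports_dropped_no_reactions = dropped_no_reac,
                invalid_fda_dt = invalid_fda)
  out <- new_report_set(demo_out, drugs, reac, outc,
                        counters = counters)
  add_provenance(out, "assemble",
                 list(n_reports = nrow(demo_out)))
}

#' Deduplicate case versions
#'
#' FAERS cases are resubmitted as new versions sharing a `caseid`; following
#' the FDA recommendation, only the most recent version of each case is kept:
#' the record with the greatest `fda_date`, ties broken by the greatest
#' `primary_id`. Output is sorted by `case_id`, making the operation
#' deterministic and idempotent.
#'
#' @param reports a `report_set`.
#' @return A `report_set` with one report per `case_id` and provenance step
#'   `"deduplicate"`.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  demo <- reports$demo
  if (nrow(demo) == 0L) {
    return(add_provenance(reports, "deduplicate"))
  }
  pid_num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", demo$primary_id)))
  if (anyNA(pid_num)) pid_num <- xtfrm(demo$primary_id)
  fda <- demo$fda_date
  fda[is.na(fda)] <- -1L   # undated versions lose to any dated one
  o <- order_radix(demo$case_id, -fda, -pid_num)
  keep_rows <- o[!duplicated(demo$case_id[o])]
  demo_kept <- demo[sort(keep_rows), , drop = FALSE]
  demo_kept <- demo_kept[order_radix(demo_kept$case_id), , drop = FALSE]
  rownames(demo_kept) <- NULL
  removed <- nrow(demo) - nrow(demo_kept)
  out <- subset_report_set(reports, demo_kept$primary_id)
  out$demo <- demo_kept
  out$counters["dedup_removed"] <-
    unname(out$counters["dedup_removed"] %0% 0L) + removed
  add_provenance(out, "deduplicate", list(removed = removed))
}

`%0%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Keep reports where the query drug is a suspect
#'
#' Retains reports containing at least one drug entry matching the query with
#' role code PS (primary suspect) or SS (secondary suspect). Reports where
#' the query drug appears only as concomitant (C) or interacting (I) are
#' excluded.
#'
#' @param reports a `report_set`.
#' @param query a [drug_query()] or character vector of drug names.
#' @return Filtered `report_set` with provenance step `"filter_suspect"`.
#' @export
filter_suspect <- function(reports, query) {
  stopifnot(inherits(reports, "report_set"))
  query <- as_drug_query(query)
  dr <- reports$drugs
  hit <- match_drug_names(norm_term(dr$drug_name), query) &
    dr$role %in% c("PS", "SS")
  keep <- unique(dr$primary_id[hit])
  out <- subset_report_set(reports, keep)
  add_provenance(out, "filter_suspect",
                 list(patterns = query$raw, mode = query$mode,
                      kept = length(keep)))
}

.default_completeness_fields <-
  c("sex", "age_years", "reporter", "fda_date", "outcomes", "country",
    "weight")

#' Exclude reports with too much missing information
#'
#' Counts missing items over an audited field set (by default sex, age,
#' reporter occupation, FDA date, outcomes, plus country and weight when those
#' columns are present) and removes reports with strictly more than
#' `max_missing` missing items.
#'
#' @param reports a `report_set`.
#' @param max_missing maximum tolerated number of missing items (default 3).
#' @param fields character vector of audited fields; fields absent from the
#'   data are ignored.
#' @return Filtered `report_set`; the audited field set is recorded in
#'   provenance.
#' @export
filter_completeness <- function(reports, max_missing = 3,
                                fields = .default_completeness_fields) {
  stopifnot(inherits(reports, "report_set"), is_count(max_missing))
  demo <- reports$demo
  audited <- character(0)
  miss <- matrix(FALSE, nrow = nrow(demo), ncol = 0)
  add <- function(name, v) {
    audited <<- c(audited, name)
    miss <<- cbind(miss, v)
  }
  if ("sex" %in% fields) add("sex", is.na(demo$sex) | demo$sex == "unknown")
  if ("age_years" %in% fields) add("age_years", is.na(demo$age_years))
  if ("reporter" %in% fields) {
    add("reporter", is.na(demo$reporter) | demo$reporter == "unknown")
  }
  if ("fda_date" %in% fields) add("fda_date", is.na(demo$fda_date))
  if ("outcomes" %in% fields) {
    add("outcomes", !(demo$primary_id %in% reports$outcomes$primary_id))
  }
  if ("country" %in% fields && "country" %in% names(demo)) {
    add("country", is.na(demo$country))
  }
  if ("weight" %in% fields && "weight" %in% names(demo)) {
    add("weight", is.na(demo$weight))
  }
  n_missing <- if (ncol(miss)) rowSums(miss) else rep(0L, nrow(demo))
  keep <- demo$primary_id[n_missing <= max_missing]
  out <- subset_report_set(reports, keep)
  add_provenance(out, "filter_completeness",
                 list(max_missing = max_missing, fields = audited,
                      removed = nrow(demo) - length(keep)))
}

#' Restrict reports to a reporting period
#'
#' Keeps reports whose `fda_date` lies in the closed interval
#' `[start, end]`, both given as integer `YYYYMMDD`.
#'
#' @param reports a `report_set`.
#' @param start,end period bounds as integer `YYYYMMDD`.
#' @return Filtered `report_set`.
#' @export
filter_period <- function(reports, start, end) {
  stopifnot(inherits(reports, "report_set"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || is.na(ymd_to_date(start)) ||
      is.na(ymd_to_date(end))) {
    stop2("filter_period: 'start' and 'end' must be valid YYYYMMDD dates")
  }
  if (start > end) stop2("filter_period: 'start' must not exceed 'end'")
  demo <- reports$demo
  keep <- demo$primary_id[!is.na(demo$fda_date) &
                            demo$fda_date >= start & demo$fda_date <= end]
  out <- subset_report_set(reports, keep)
  add_provenance(out, "filter_period",
                 list(start = start, end = end,
                      removed = nrow(demo) - length(keep)))
}

#' Write a normalised report table with a provenance sidecar
#'
#' Serialises a `report_set` to a single one-row-per-report CSV (drug,
#' reaction and outcome lists joined with `";"`) plus a JSON sidecar
#' recording the ordered filter provenance and counters.
#'
#' @param reports a `report_set`.
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".provenance.json")`.
#' @return Invisibly, the CSV path.
#' @export
write_report_set <- function(reports, path) {
  stopifnot(inherits(reports, "report_set"))
  demo <- reports$demo
  join <- function(tab, fmt) {
    v <- vapply(split(fmt(tab), tab$primary_id), paste, character(1),
                collapse = ";")
    out <- v[demo$primary_id]
    out[is.na(out)] <- ""
    unname(out)
  }
  demo$drugs <- join(reports$drugs,
                     function(t) paste0(t$drug_name, "(", t$role, ")"))
  demo$reactions <- join(reports$reactions, function(t) t$pt)
  demo$outcomes <- join(reports$outcomes, function(t) t$outc_cod)
  utils::write.csv(demo, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(provenance = reports$provenance,
         counters = as.list(reports$counters)),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
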