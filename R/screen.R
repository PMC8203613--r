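# Whole-database screens: one disproportionality evaluation per term at a
# chosen MedDRA level, plus descriptive summaries and serialization.

check_screen_ready <- function(reports) {
  if (!has_provenance(reports, "deduplicate")) {
    stop2("pipeline-order error: reports must pass deduplicate() before ",
          "screening (case versions would inflate the counts)")
  }
}

# Tabulate the target/other pair counts per group (term). `group` is a
# character vector parallel to the pair frame; NA rows are excluded.
tabulate_groups <- function(pf, group, unit) {
  keep <- !is.na(group)
  pf <- pf[keep, , drop = FALSE]
  group <- group[keep]
  if (unit == "report") {
    key <- !duplicated(paste(pf$primary_id, group, sep = "\r"))
    pf <- pf[key, , drop = FALSE]
    group <- group[key]
  }
  terms <- sort(unique(group), method = "radix")
  at <- table(factor(group[pf$target], levels = terms))
  ot <- table(factor(group[!pf$target], levels = terms))
  data.frame(term = terms, a = as.integer(at), c_ = as.integer(ot),
             stringsAsFactors = FALSE)
}

#' Screen every term at a MedDRA level for one drug
#'
#' Builds the contingency table and the three disproportionality statistics
#' for each term observed at the requested level, and applies the combined
#' signal criteria. Rows are emitted for all terms with at least one target
#' or background occurrence (n >= 1 among target pairs is not required), so
#' downstream counts of "suspicious signals" are a filter on the output, and
#' the screen remains audit-complete. Rows with `n < min_n` carry
#' all-negative evaluations. Output order is deterministic: descending `n`,
#' then term name.
#'
#' The input must have passed [deduplicate()]; screening a report set whose
#' provenance lacks that step is refused.
#'
#' @param reports a deduplicated `report_set` (the whole database, not the
#'   suspect-filtered subset: the comparator cells c and d come from all
#'   other drugs' reports).
#' @param query a [drug_query()] or character vector.
#' @param level `"pt"`, `"smq"` or `"soc"`.
#' @param dict a `term_dictionary`; required for SOC/SMQ levels. At PT level
#'   a dictionary is optional and PTs absent from it are still screened.
#' @param criteria a [signal_criteria()].
#' @param unit `"pair"` (default) or `"report"` counting unit.
#' @param yates,orientation passed to the PRR/chi-squared computation.
#' @return A data frame of class `faers_screen` with columns `term`,
#'   `level`, `n`, `a`, `b`, `c`, `d`, the statistics, the three positivity
#'   flags, `combined_pos` and `label`.
#' @export
run_screen <- function(reports, query, level = "pt", dict = NULL,
                       criteria = signal_criteria(),
                       unit = c("pair", "report"),
                       yates = FALSE, orientation = c("row", "column")) {
  check_screen_ready(reports)
  unit <- match.arg(unit)
  level <- check_level(level)
  orientation <- match.arg(orientation)
  query <- as_drug_query(query)
  pf <- pair_frame(reports, query)

  empty <- data.frame(term = character(0), level = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
  if (nrow(pf) == 0L) {
    return(structure(empty, class = c("faers_screen", "data.frame"),
                     drug = paste(query$raw, collapse = "|"), level = level,
                     unit = unit, criteria = criteria))
  }

  target_ids <- unique(pf$primary_id[pf$target])
  n_target_reports <- length(target_ids)
  n_all_reports <- nrow(reports$demo)
  total_target <- if (unit == "pair") sum(pf$target) else n_target_reports
  total_other <- if (unit == "pair") sum(!pf$target) else
    n_all_reports - n_target_reports

  if (level == "pt") {
    tab <- tabulate_groups(pf, pf$pt_norm, unit)
    display <- pf$pt[match(tab$term, pf$pt_norm)]
  } else if (level == "soc") {
    if (is.null(dict)) stop2("run_screen: SOC level requires a dictionary")
    soc <- pt_soc_lookup(dict, pf$pt_norm)
    tab <- tabulate_groups(pf, soc, unit)
    display <- dict$pt$soc[match(tab$term, dict$pt$soc_norm)]
  } else {
    if (is.null(dict)) stop2("run_screen: SMQ level requires a dictionary")
    rows <- lapply(names(dict$smq), function(nm) {
      m <- pf$pt_norm %in% dict$smq[[nm]]
      sub <- pf[m, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      g <- rep(norm_term(nm), nrow(sub))
      out <- tabulate_groups(sub, g, unit)
      out$term <- nm
      out
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) {
      tab <- data.frame(term = character(0), a = integer(0),
                        c_ = integer(0), stringsAsFactors = FALSE)
    } else {
      tab <- do.call(rbind, rows)
    }
    display <- tab$term
  }

  if (nrow(tab) == 0L) {
    return(structure(empty, class = c("faers_screen", "data.frame"),
                     drug = paste(query$raw, collapse = "|"), level = level,
                     unit = unit, criteria = criteria))
  }

  a <- tab$a; c_ <- tab$c_
  b <- total_target - a; d <- total_other - c_
  st <- dispro_cells(a, b, c_, d, correction = "haldane-on-zero",
                     yates = yates, orientation = orientation)

  ror_pos <- st$ror_ci_low > criteria$ror_ci_low
  prr_pos <- st$prr >= criteria$prr_min & st$chi2 >= criteria$chi2_min
  ic_pos <- st$ic_minus_2sd > criteria$ic_minus_2sd_min
  low_n <- a < criteria$min_n
  ror_pos[low_n] <- prr_pos[low_n] <- ic_pos[low_n] <- FALSE

  res <- data.frame(
    term = display, level = level, n = a,
    a = a, b = b, c = c_, d = d,
    ror = st$ror, ror_ci_low = st$ror_ci_low, ror_ci_high = st$ror_ci_high,
    prr = st$prr, chi2 = st$chi2,
    ic = st$ic, ic_2sd = st$ic_minus_2sd, point_ic = st$point_ic,
    ror_pos = ror_pos, prr_pos = prr_pos, ic_pos = ic_pos,
    combined_pos = ror_pos & prr_pos & ic_pos,
    label = "unknown",
    stringsAsFactors = FALSE)
  res <- res[order_radix(-res$n, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("faers_screen", "data.frame"),
            drug = paste(query$raw, collapse = "|"), level = level,
            unit = unit, criteria = criteria,
            total_target = total_target, total_other = total_other)
}

#' @export
print.faers_screen <- function(x, n_show = 10L, ...) {
  cat("<faers_screen>", attr(x, "drug"), "@", attr(x, "level"),
      "level,", attr(x, "unit"), "unit;", nrow(x), "terms,",
      sum(x$combined_pos), "combined-positive\n")
  if (nrow(x) > 0L) {
    top <- utils::head(x, n_show)
    disp <- data.frame(
      term = top$term, N = top$n,
      `ROR (95%CI)` = sprintf("%.2f (%.2f-%.2f)", top$ror, top$ror_ci_low,
                              top$ror_ci_high),
      `PRR (chi2)` = sprintf("%.2f (%.2f)", top$prr, top$chi2),
      `IC (IC-2SD)` = sprintf("%.2f (%.2f)", top$ic, top$ic_2sd),
      signal = ifelse(top$combined_pos, "yes", "no"),
      check.names = FALSE)
    print(disp, row.names = FALSE)
    if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more terms\n")
  }
  invisible(x)
}

#' @export
summary.faers_screen <- function(object, ...) {
  out <- list(drug = attr(object, "drug"), level = attr(object, "level"),
              unit = attr(object, "unit"), n_terms = nrow(object),
              n_combined_positive = sum(object$combined_pos),
              positive_terms = object$term[object$combined_pos])
  class(out) <- "summary.faers_screen"
  out
}

#' @export
print.summary.faers_screen <- function(x, ...) {
  cat("Screen of", x$drug, "at", x$level, "level (", x$unit, "unit):",
      x$n_terms, "terms,", x$n_combined_positive, "combined-positive\n")
  if (length(x$positive_terms)) {
    cat("  positives:", paste(x$positive_terms, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Compare screens across drug queries on a fixed PT list
#'
#' Runs a PT-level screen per named query, restricted to the given PT list;
#' terms absent from a query's reports appear with `n = 0` and an
#' all-negative evaluation, so every query yields one row per requested
#' term.
#'
#' @param reports a deduplicated `report_set`.
#' @param queries named list of [drug_query()] objects (or character
#'   vectors); at least two, with unique names.
#' @param terms character vector of PTs to compare.
#' @param dict optional `term_dictionary`.
#' @param criteria a [signal_criteria()].
#' @param unit counting unit.
#' @return Named list of class `faers_comparison`, one screen data frame per
#'   query.
#' @export
run_drug_comparison <- function(reports, queries, terms, dict = NULL,
                                criteria = signal_criteria(),
                                unit = c("pair", "report")) {
  unit <- match.arg(unit)
  if (length(queries) < 2L) {
    stop2("run_drug_comparison: at least two named queries are required")
  }
  nms <- names(queries)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop2("run_drug_comparison: every query must be named")
  }
  if (anyDuplicated(nms)) {
    stop2("run_drug_comparison: query names must be unique (overlap: ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "), ")")
  }
  terms_n <- norm_term(terms)
  template <- data.frame(
    term = NA_character_, level = "pt", n = 0L, a = 0L, b = NA_real_,
    c = NA_real_, d = NA_real_, ror = NA_real_, ror_ci_low = NA_real_,
    ror_ci_high = NA_real_, prr = NA_real_, chi2 = NA_real_, ic = NA_real_,
    ic_2sd = NA_real_, point_ic = NA_real_, ror_pos = FALSE,
    prr_pos = FALSE, ic_pos = FALSE, combined_pos = FALSE,
    label = "unknown", stringsAsFactors = FALSE)
  out <- lapply(queries, function(q) {
    sc <- run_screen(reports, q, level = "pt", dict = dict,
                     criteria = criteria, unit = unit)
    if (nrow(sc) == 0L) {
      res <- template[rep(1L, length(terms)), , drop = FALSE]
      res$term <- terms
      rownames(res) <- NULL
      return(structure(res, class = c("faers_screen", "data.frame"),
                       drug = attr(sc, "drug"), level = "pt", unit = unit,
                       criteria = criteria))
    }
    idx <- match(terms_n, norm_term(sc$term))
    res <- sc[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    missing <- is.na(idx)
    if (any(missing)) {
      res$term[missing] <- terms[missing]
      res$n[missing] <- res$a[missing] <- 0L
      num_cols <- c("b", "c", "d", "ror", "ror_ci_low", "ror_ci_high",
                    "prr", "chi2", "ic", "ic_2sd", "point_ic")
      for (cn in num_cols) res[[cn]][missing] <- NA_real_
      for (cn in c("ror_pos", "prr_pos", "ic_pos", "combined_pos")) {
        res[[cn]][missing] <- FALSE
      }
      res$level[missing] <- "pt"
      res$label[missing] <- "unknown"
    }
    res$term <- terms  # keep the caller's spellings and order
    rownames(res) <- NULL
    structure(res, class = c("faers_screen", "data.frame"),
              drug = attr(sc, "drug"), level = "pt", unit = unit,
              criteria = criteria)
  })
  structure(out, class = "faers_comparison")
}

#' @export
print.faers_comparison <- function(x, ...) {
  cat("<faers_comparison> of", length(x), "drug queries\n")
  for (nm in names(x)) {
    cat("\n==", nm, "==\n")
    print(x[[nm]], n_show = length(x[[nm]]$term))
  }
  invisible(x)
}

#' Descriptive summary of a report set
#'
#' Computes report and event totals, events per report, and count/percentage
#' breakdowns by sex, age group, reporter occupation and outcome code, plus
#' the serious adverse event (SAE) share. A report is an SAE when it carries
#' at least one outcome among DE (death), LT (life-threatening), HO
#' (hospitalisation, initial or prolonged) or DS (disability). Percentages
#' are computed on the report total and rounded half-up to two decimals.
#'
#' @param reports a deduplicated `report_set`.
#' @return Object of class `descriptive_summary`.
#' @export
descriptive_summary <- function(reports) {
  check_screen_ready(reports)
  demo <- reports$demo
  n <- nrow(demo)
  n_events <- nrow(reports$reactions)
  pct <- function(k) round_half_up(100 * k / n, 2)
  breakdown <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    data.frame(category = levels, count = as.integer(counts),
               percent = if (n > 0) pct(as.integer(counts)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  sex <- breakdown(demo$sex, c("male", "female", "unknown"))
  age <- breakdown(demo$age_group,
                   c("<18", "18-44", "45-64", "65-74", ">=75", "unknown"))
  reporter <- breakdown(demo$reporter,
                        c("doctor", "pharmacist", "other-medical", "lawyer",
                          "consumer", "unknown"))
  outc <- reports$outcomes
  outcomes <- data.frame(category = .outcome_codes,
                         count = as.integer(table(factor(outc$outc_cod,
                                                         levels = .outcome_codes))),
                         stringsAsFactors = FALSE)
  outcomes$percent <- if (n > 0) pct(outcomes$count) else NA_real_
  sae_ids <- unique(outc$primary_id[outc$outc_cod %in% .sae_codes])
  sae_count <- sum(demo$primary_id %in% sae_ids)
  # Presentation grouping used in some summary texts: 18-60 as the union of
  # the 18-44 and 45-64 bins.
  a1860 <- sum(age$count[age$category %in% c("18-44", "45-64")])
  structure(list(
    n_reports = n,
    n_events = n_events,
    events_per_report = if (n > 0) n_events / n else NA_real_,
    sex = sex, age_group = age,
    age_18_60 = list(count = a1860,
                     percent = if (n > 0) pct(a1860) else NA_real_),
    reporter = reporter, outcomes = outcomes,
    sae = list(count = sae_count,
               percent = if (n > 0) pct(sae_count) else NA_real_)),
    class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("<descriptive_summary>\n")
  cat(sprintf("  reports: %d; events: %d; events/report: %s\n",
              x$n_reports, x$n_events,
              if (is.na(x$events_per_report)) "NA" else
                sprintf("%.2f", round_half_up(x$events_per_report, 2))))
  show <- function(name, tab) {
    cat(" ", name, "\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-14s %6d  %6.2f%%\n", tab$category[i], tab$count[i],
                  tab$percent[i]))
    }
  }
  show("Sex", x$sex)
  show("Age group (y)", x$age_group)
  show("Reporters", x$reporter)
  show("Outcomes", x$outcomes)
  cat(sprintf("  SAEs: %d (%.2f%%)\n", x$sae$count, x$sae$percent))
  invisible(x)
}

#' Annotate screen rows with drug-label membership
#'
#' Sets `label` to `"yes"` for terms contained (case-normalised) in the
#' supplied label PT set and `"no"` otherwise.
#'
#' @param rows a `faers_screen` (or compatible data frame with a `term`
#'   column).
#' @param label_terms character vector of labelled PTs.
#' @return `rows` with the `label` column filled.
#' @export
annotate_labels <- function(rows, label_terms) {
  stopifnot(is.data.frame(rows), "term" %in% names(rows))
  rows$label <- ifelse(norm_term(rows$term) %in% norm_term(label_terms),
                       "yes", "no")
  rows
}

.screen_columns <- c("term", "level", "n", "ror", "ror_ci_low",
                     "ror_ci_high", "prr", "chi2", "ic", "ic_2sd",
                     "ror_pos", "prr_pos", "ic_pos", "combined_pos", "label")

#' Write a screen to CSV, TSV or JSON
#'
#' Serialises the fixed audit column set (`term, level, n, ror, ror_ci_low,
#' ror_ci_high, prr, chi2, ic, ic_2sd, ror_pos, prr_pos, ic_pos,
#' combined_pos, label`). Floats are written at full precision by default;
#' `digits = 2` produces the two-decimal presentation variant used in
#' published tables.
#'
#' @param rows a `faers_screen` or compatible data frame.
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @param digits `NULL` for full precision or an integer for rounded
#'   presentation output.
#' @return Invisibly, `path`.
#' @export
write_screen <- function(rows, path, format = c("csv", "tsv", "json"),
                         digits = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(.screen_columns, names(rows))
  if (length(missing_cols)) {
    stop2("write_screen: rows lack column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(rows)[, .screen_columns, drop = FALSE]
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) &
      !(names(out) %in% c("n"))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  res <- tryCatch(
    switch(format,
      csv = utils::write.csv(out, path, row.names = FALSE, na = ""),
      tsv = utils::write.table(out, path, sep = "\t", row.names = FALSE,
                               quote = FALSE, na = ""),
      json = jsonlite::write_json(out, path, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA, na = "null")),
    error = function(e) stop2("write_screen: failed writing '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a screening configuration file
#'
#' YAML configuration with optional blocks `criteria` (threshold overrides
#' for [signal_criteria()]), `completeness` (`max_missing`, `fields`),
#' `queries` (named lists with `patterns` and optional `mode`), `period`
#' (`start`, `end`) and `labels` (PT list).
#'
#' @param path YAML file path.
#' @return List with elements `criteria` (a `signal_criteria`),
#'   `completeness`, `queries` (named list of `drug_query`), `period`,
#'   `labels`.
#' @export
read_screen_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  crit <- do.call(signal_criteria, cfg$criteria %||% list())
  queries <- lapply(cfg$queries %||% list(), function(q) {
    if (is.character(q)) drug_query(q)
    else drug_query(q$patterns, mode = q$mode %||% "exact")
  })
  list(criteria = crit,
       completeness = cfg$completeness %||% list(max_missing = 3),
       queries = queries,
       period = cfg$period,
       labels = cfg$labels %||% character(0))
}
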