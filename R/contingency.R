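#' Construct a 2x2 contingency table
#'
#' Holds the four cells of the disproportionality table for a (drug, term)
#' pair: `a` target drug & target event, `b` target drug & other events,
#' `c` other drugs & target event, `d` other drugs & other events. The
#' counting unit is either the deduplicated report or the (report, PT) pair.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @param unit `"pair"` or `"report"`.
#' @param drug,term,level optional labels carried for display.
#' @param integer_cells require integer cells (TRUE for observed tables;
#'   expected tables under a generative model may be fractional).
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, unit = c("pair", "report"),
                              drug = NA_character_, term = NA_character_,
                              level = NA_character_, integer_cells = TRUE) {
  unit <- match.arg(unit)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop2("contingency_table: cells must be finite and nonnegative")
  }
  if (integer_cells && any(cells != floor(cells))) {
    stop2("contingency_table: cells must be integers")
  }
  if (sum(cells) <= 0) stop2("contingency_table: N = a+b+c+d must be > 0")
  structure(list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
                 n = unname(sum(cells)), unit = unit, drug = drug,
                 term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  lbl <- if (!is.na(x$term)) paste0(" [", x$drug, " x ", x$term, " @ ",
                                    x$level, "]") else ""
  cat("<contingency_table>", x$unit, "unit", lbl, "\n")
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("target drug", "other drugs"),
                         c("target event", "other events")))
}

# Internal: one row per (report, reaction PT) pair, flagged target when the
# report carries the query drug in a suspect role (PS/SS).
pair_frame <- function(reports, query) {
  stopifnot(inherits(reports, "report_set"))
  query <- as_drug_query(query)
  dr <- reports$drugs
  hit <- match_drug_names(norm_term(dr$drug_name), query) &
    dr$role %in% c("PS", "SS")
  target_ids <- unique(dr$primary_id[hit])
  rx <- reports$reactions
  data.frame(primary_id = rx$primary_id,
             pt = rx$pt,
             pt_norm = norm_term(rx$pt),
             target = rx$primary_id %in% target_ids,
             stringsAsFactors = FALSE)
}

#' Enumerate (report, PT) pairs for a drug query
#'
#' Each pair is flagged "target" when its report contains the query drug in
#' a suspect role (PS/SS). This is the counting unit behind the default
#' contingency tables.
#'
#' @param reports a deduplicated `report_set`.
#' @param query a [drug_query()] or character vector of drug names.
#' @return List of class `pair_counts`: `total_pairs`, `target_pairs`, and
#'   `per_pt`, a data frame of per-PT tallies in both strata.
#' @export
pair_counts <- function(reports, query) {
  pf <- pair_frame(reports, query)
  if (nrow(pf) == 0L) {
    per_pt <- data.frame(pt = character(0), target = integer(0),
                         other = integer(0), stringsAsFactors = FALSE)
  } else {
    tgt <- table(pf$pt_norm[pf$target])
    oth <- table(pf$pt_norm[!pf$target])
    pts <- sort(unique(pf$pt_norm), method = "radix")
    display <- pf$pt[match(pts, pf$pt_norm)]
    per_pt <- data.frame(
      pt = display,
      target = as.integer(tgt[pts]),
      other = as.integer(oth[pts]),
      stringsAsFactors = FALSE)
    per_pt$target[is.na(per_pt$target)] <- 0L
    per_pt$other[is.na(per_pt$other)] <- 0L
  }
  structure(list(total_pairs = nrow(pf),
                 target_pairs = sum(pf$target),
                 per_pt = per_pt),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts>", x$total_pairs, "pairs,", x$target_pairs,
      "target;", nrow(x$per_pt), "distinct PTs\n")
  invisible(x)
}

# Internal: logical match of each pair row against a term at a level.
match_pairs_at_level <- function(pf, term, level, dict) {
  level <- check_level(level)
  term_n <- norm_term(term)
  if (level == "pt") {
    return(pf$pt_norm == term_n)
  }
  if (is.null(dict)) stop2("a term_dictionary is required at SOC/SMQ level")
  if (level == "soc") {
    if (!(term_n %in% dict$pt$soc_norm)) {
      stop2("build_table: unknown SOC '", term, "'")
    }
    soc <- pt_soc_lookup(dict, pf$pt_norm)
    return(!is.na(soc) & soc == term_n)
  }
  idx <- match(term_n, norm_term(names(dict$smq)))
  if (is.na(idx)) stop2("build_table: unknown SMQ '", term, "'")
  pf$pt_norm %in% dict$smq[[idx]]
}

#' Build the 2x2 contingency table for a (drug, term, level) triple
#'
#' With the default `"pair"` unit, every (report, reaction PT) pair is
#' classified by its own PT, so cells sum exactly to the total pair count.
#' With the `"report"` unit, a report counts in `a` when any of its PTs
#' matches the term. Reports where the target drug appears only in
#' non-suspect roles fall in the "other drugs" stratum.
#'
#' @param reports a deduplicated `report_set`.
#' @param query a [drug_query()] or character vector.
#' @param term term name at the given level.
#' @param level `"pt"`, `"smq"` or `"soc"`.
#' @param dict a `term_dictionary`; may be NULL for PT-level tables.
#' @param unit `"pair"` (default) or `"report"`.
#' @return A `contingency_table`.
#' @export
build_table <- function(reports, query, term, level = "pt", dict = NULL,
                        unit = c("pair", "report")) {
  unit <- match.arg(unit)
  query <- as_drug_query(query)
  pf <- pair_frame(reports, query)
  m <- match_pairs_at_level(pf, term, level, dict)
  if (unit == "pair") {
    a <- sum(pf$target & m); b <- sum(pf$target & !m)
    c_ <- sum(!pf$target & m); d <- sum(!pf$target & !m)
  } else {
    ids <- reports$demo$primary_id
    tgt <- ids %in% pf$primary_id[pf$target]
    hit <- ids %in% pf$primary_id[m]
    a <- sum(tgt & hit); b <- sum(tgt & !hit)
    c_ <- sum(!tgt & hit); d <- sum(!tgt & !hit)
  }
  contingency_table(a, b, c_, d, unit = unit,
                    drug = paste(query$raw, collapse = "|"),
                    term = as.character(term),
                    level = check_level(level))
}
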