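#' Construct a term dictionary
#'
#' A term dictionary maps each preferred term (PT) to exactly one system
#' organ class (SOC) and defines named narrow standardised query (SMQ)
#' membership sets. Lookups are case-insensitive on whitespace-normalised
#' names. Validation is strict: a PT mapped to two SOCs, an SMQ member PT
#' absent from the PT map, or an empty SMQ set are all fatal.
#'
#' @param pt_to_soc data frame with columns `pt` and `soc`.
#' @param smq_narrow named list of character vectors: SMQ name -> member PTs
#'   (narrow scope). May be empty.
#' @param version_tag free-text version label.
#' @return An object of class `term_dictionary`.
#' @seealso [load_dictionary()], [terms_at_level()], [event_matches()]
#' @export
term_dictionary <- function(pt_to_soc, smq_narrow = list(),
                            version_tag = "unversioned") {
  stopifnot(is.data.frame(pt_to_soc), all(c("pt", "soc") %in% names(pt_to_soc)))
  pt <- data.frame(pt = trimws(as.character(pt_to_soc$pt)),
                   soc = trimws(as.character(pt_to_soc$soc)),
                   stringsAsFactors = FALSE)
  pt$pt_norm <- norm_term(pt$pt)
  pt$soc_norm <- norm_term(pt$soc)
  pt <- pt[!duplicated(paste(pt$pt_norm, pt$soc_norm, sep = "\r")), ,
           drop = FALSE]
  conflicts <- unique(pt$pt[duplicated(pt$pt_norm) |
                              duplicated(pt$pt_norm, fromLast = TRUE)])
  if (length(conflicts) > 0L) {
    stop2("term_dictionary: PT(s) mapped to more than one SOC: ",
          paste(conflicts, collapse = ", "))
  }
  soc_spellings <- unique(pt[, c("soc", "soc_norm")])
  dup_soc <- soc_spellings$soc[duplicated(soc_spellings$soc_norm) |
                                 duplicated(soc_spellings$soc_norm,
                                            fromLast = TRUE)]
  if (length(dup_soc) > 0L) {
    stop2("term_dictionary: SOC spellings collide after case-normalisation: ",
          paste(dup_soc, collapse = ", "))
  }
  rownames(pt) <- NULL

  if (length(smq_narrow) > 0L) {
    if (is.null(names(smq_narrow)) || any(!nzchar(names(smq_narrow)))) {
      stop2("term_dictionary: every SMQ must be named")
    }
    if (anyDuplicated(norm_term(names(smq_narrow)))) {
      stop2("term_dictionary: SMQ names collide after case-normalisation")
    }
    for (nm in names(smq_narrow)) {
      raw_members <- unique(trimws(smq_narrow[[nm]]))
      raw_members <- raw_members[nzchar(raw_members)]
      if (length(raw_members) == 0L) {
        stop2("term_dictionary: SMQ '", nm, "' has no member PTs")
      }
      members <- unique(norm_term(raw_members))
      unknown <- raw_members[!(norm_term(raw_members) %in% pt$pt_norm)]
      if (length(unknown) > 0L) {
        stop2("term_dictionary: SMQ '", nm,
              "' references PT(s) absent from the PT->SOC map: ",
              paste(unknown, collapse = ", "))
      }
      smq_narrow[[nm]] <- members
    }
  }
  structure(list(pt = pt, smq = smq_narrow, version_tag = version_tag),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>", x$version_tag, "\n ",
      nrow(x$pt), "PTs;", length(unique(x$pt$soc_norm)), "SOCs;",
      length(x$smq), "narrow SMQs\n")
  invisible(x)
}

#' Load a term dictionary from a two-section file
#'
#' The dictionary file format has two CSV sections introduced by the literal
#' headers `[PT_SOC]` (rows `pt,soc`) and `[SMQ_PT]` (rows `smq,pt`; the
#' section may be absent). Lines starting with `#` are comments. A small
#' synthetic dictionary is bundled with the package, see
#' [pvsignal_dictionary()].
#'
#' @param path path to the dictionary file.
#' @param version_tag optional version label; defaults to the file name.
#' @return A validated `term_dictionary`.
#' @export
load_dictionary <- function(path, version_tag = basename(path)) {
  if (!file.exists(path)) stop2("dictionary file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- trimws(lines[grepl("^\\[", lines)])
  parse_section <- function(name, cols) {
    idx <- which(headers == name)
    if (length(idx) == 0L) return(NULL)
    body <- lines[sec == idx & !grepl("^\\[", lines)]
    if (length(body) == 0L) return(NULL)
    tab <- utils::read.csv(text = body, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = cols, comment.char = "")
    tab
  }
  pt_tab <- parse_section("[PT_SOC]", c("pt", "soc"))
  if (is.null(pt_tab)) {
    stop2("dictionary file '", path, "' has no [PT_SOC] section")
  }
  smq_tab <- parse_section("[SMQ_PT]", c("smq", "pt"))
  smq <- list()
  if (!is.null(smq_tab)) {
    smq <- lapply(split(trimws(smq_tab$pt), trimws(smq_tab$smq)), unique)
  }
  term_dictionary(pt_tab, smq, version_tag = version_tag)
}

#' Path to the bundled synthetic dictionary
#'
#' Returns the path of the synthetic MedDRA-like dictionary shipped with the
#' package (40 PTs, 8 SOCs, 5 narrow SMQs). The vocabulary uses real-world
#' term spellings but is a synthetic fixture, not an extract of the licensed
#' MedDRA dictionary.
#'
#' @return File path (character).
#' @export
pvsignal_dictionary <- function() {
  system.file("extdata", "synthetic_meddra_dictionary.csv",
              package = "pvsignal", mustWork = TRUE)
}

.levels <- c("pt", "smq", "soc")

check_level <- function(level) {
  level <- tolower(as.character(level))
  match.arg(level, .levels)
}

#' List terms available at an aggregation level
#'
#' @param dict a `term_dictionary`.
#' @param level `"pt"`, `"smq"` or `"soc"`.
#' @return Sorted character vector of term names (original spellings).
#' @export
terms_at_level <- function(dict, level) {
  stopifnot(inherits(dict, "term_dictionary"))
  level <- check_level(level)
  out <- switch(level,
    pt = dict$pt$pt,
    soc = unique(dict$pt$soc),
    smq = names(dict$smq))
  sort(unique(out), method = "radix")
}

# Normalised SOC of each normalised PT (NA when unmapped).
pt_soc_lookup <- function(dict, pt_norm) {
  dict$pt$soc_norm[match(pt_norm, dict$pt$pt_norm)]
}

#' Test whether a report's reactions match a term at a level
#'
#' At PT level the test is set membership among the report's reaction PTs
#' (a PT absent from the dictionary still matches at PT level). At SOC level
#' the report matches if any reaction PT maps to the SOC; at SMQ level, if
#' any reaction PT belongs to the SMQ's narrow member set. Reaction PTs not
#' found in the dictionary are returned as `unmapped` and never match at
#' SOC/SMQ level.
#'
#' @param dict a `term_dictionary`.
#' @param reactions character vector of reaction PTs (one report).
#' @param term the query term.
#' @param level `"pt"`, `"smq"` or `"soc"`.
#' @return List with `match` (logical), `matched_pts` (the reaction PTs that
#'   matched) and `unmapped` (reaction PTs absent from the dictionary).
#' @export
event_matches <- function(dict, reactions, term, level) {
  stopifnot(inherits(dict, "term_dictionary"))
  level <- check_level(level)
  term_n <- norm_term(term)
  rx <- unique(reactions)
  rx_n <- norm_term(rx)
  unmapped <- rx[!(rx_n %in% dict$pt$pt_norm)]
  hit <- switch(level,
    pt = rx_n == term_n,
    soc = {
      if (!(term_n %in% dict$pt$soc_norm)) {
        stop2("event_matches: unknown SOC '", term, "'")
      }
      !is.na(pt_soc_lookup(dict, rx_n)) &
        pt_soc_lookup(dict, rx_n) == term_n
    },
    smq = {
      idx <- match(term_n, norm_term(names(dict$smq)))
      if (is.na(idx)) stop2("event_matches: unknown SMQ '", term, "'")
      rx_n %in% dict$smq[[idx]]
    })
  list(match = any(hit), matched_pts = rx[hit], unmapped = unmapped)
}
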