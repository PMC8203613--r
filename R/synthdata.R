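# Synthetic FAERS-like report generator with known ground truth.
#
# The generative model, per case:
#   * suspect drugs drawn independently with per-drug probabilities (at
#     least one enforced by a probability-weighted fallback draw);
#   * a distinct-event count driven by a zero-truncated Poisson draw, with
#     the Poisson rate calibrated so the expected number of DISTINCT
#     reaction PTs per report equals the configured mean (set collapse of
#     repeated draws is accounted for);
#   * reaction PTs sampled by background weights, multiplied by the
#     relative risk of any injected association whose drug is suspect in
#     the report;
#   * a second case version emitted with probability duplicate_rate, sharing
#     the case id with a later FDA date (exercises deduplication);
#   * MCAR missingness per demographic field.

.default_drugs <- function() {
  data.frame(name = paste0("drug_", letters[1:8]),
             p_suspect = c(0.20, 0.10, 0.05, 0.05, 0.02, 0.02, 0.01, 0.01),
             stringsAsFactors = FALSE)
}

.default_pts <- function() {
  dict <- load_dictionary(pvsignal_dictionary())
  data.frame(pt = dict$pt$pt, weight = 1 / nrow(dict$pt),
             stringsAsFactors = FALSE)
}

#' Configure the synthetic report generator
#'
#' @param n_reports number of distinct cases to generate.
#' @param drugs data frame with columns `name` and `p_suspect` (per-report
#'   probability that the drug appears in a suspect role). Default: eight
#'   drugs with prevalences from 20\% down to 1\%.
#' @param pts data frame with columns `pt` and `weight` (background event
#'   sampling weights). Default: the 40 PTs of the bundled dictionary,
#'   equally weighted.
#' @param mean_events_per_report target mean number of distinct reaction PTs
#'   per report (default 2.53, a typical spontaneous-report average).
#' @param associations `NULL`, or data frame with columns `drug`, `pt`,
#'   `rr`: injected drug-event associations; `rr` multiplies the event's
#'   sampling weight in reports where the drug is suspect.
#' @param duplicate_rate probability that a case emits a second, later
#'   version (default 0.05).
#' @param missingness named numeric vector of per-field missingness
#'   probabilities for `sex`, `age`, `reporter` (MCAR). Defaults mirror the
#'   high unknown-age share typical of spontaneous reports.
#' @param concomitant_rate probability of one additional concomitant-role
#'   drug entry per report (default 0.3).
#' @param seed integer RNG seed; every draw is reproducible from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_reports,
                              drugs = .default_drugs(),
                              pts = .default_pts(),
                              mean_events_per_report = 2.53,
                              associations = NULL,
                              duplicate_rate = 0.05,
                              missingness = c(sex = 0.17, age = 0.42,
                                              reporter = 0.03),
                              concomitant_rate = 0.3,
                              seed = 1L) {
  if (!is_count(n_reports) || n_reports < 1) {
    stop2("simulation_config: n_reports must be a count >= 1")
  }
  stopifnot(is.data.frame(drugs), all(c("name", "p_suspect") %in% names(drugs)),
            is.data.frame(pts), all(c("pt", "weight") %in% names(pts)))
  if (any(drugs$p_suspect < 0 | drugs$p_suspect > 1)) {
    stop2("simulation_config: p_suspect must lie in [0, 1]")
  }
  if (sum(drugs$p_suspect) <= 0) {
    stop2("simulation_config: at least one drug needs p_suspect > 0")
  }
  if (any(pts$weight <= 0)) stop2("simulation_config: weights must be > 0")
  if (anyDuplicated(norm_term(drugs$name)) ||
      anyDuplicated(norm_term(pts$pt))) {
    stop2("simulation_config: drug and PT vocabularies must be unique")
  }
  m <- mean_events_per_report
  if (!is.numeric(m) || m <= 1 || m >= nrow(pts)) {
    stop2("simulation_config: mean_events_per_report must lie in ",
          "(1, number of PTs)")
  }
  miss <- c(sex = 0, age = 0, reporter = 0)
  miss[names(missingness)] <- missingness
  if (any(miss < 0 | miss > 1) || duplicate_rate < 0 || duplicate_rate > 1 ||
      concomitant_rate < 0 || concomitant_rate > 1) {
    stop2("simulation_config: rates must lie in [0, 1]")
  }
  if (!is.null(associations)) {
    stopifnot(is.data.frame(associations),
              all(c("drug", "pt", "rr") %in% names(associations)))
    if (any(associations$rr <= 0)) {
      stop2("simulation_config: relative risks must be > 0")
    }
    bad_d <- setdiff(norm_term(associations$drug), norm_term(drugs$name))
    bad_p <- setdiff(norm_term(associations$pt), norm_term(pts$pt))
    if (length(bad_d)) stop2("unknown association drug(s): ",
                             paste(bad_d, collapse = ", "))
    if (length(bad_p)) stop2("unknown association PT(s): ",
                             paste(bad_p, collapse = ", "))
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs, pts = pts,
                 mean_events_per_report = m, associations = associations,
                 duplicate_rate = duplicate_rate, missingness = miss,
                 concomitant_rate = concomitant_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>", x$n_reports, "reports;",
      nrow(x$drugs), "drugs;", nrow(x$pts), "PTs; mean events",
      x$mean_events_per_report, "; seed", x$seed, "\n")
  if (!is.null(x$associations)) {
    cat("  injected:",
        paste(sprintf("%s x %s (RR %g)", x$associations$drug,
                      x$associations$pt, x$associations$rr),
              collapse = "; "), "\n")
  }
  invisible(x)
}

# P(a given PT is drawn at least once in a report) under K ~ ZTP(lambda)
# draws with multinomial share q: 1 - E[(1-q)^K]. Numerically stable form.
ztp_inclusion <- function(lambda, q) {
  1 - exp(-lambda * q) * (1 - exp(-lambda * (1 - q))) / (1 - exp(-lambda))
}

# Calibrate the ZTP rate so the expected number of DISTINCT PTs per report
# (sum of inclusion probabilities) equals the target mean.
ztp_calibrate <- function(target_mean, weights) {
  q <- weights / sum(weights)
  f <- function(l) sum(ztp_inclusion(l, q)) - target_mean
  stats::uniroot(f, lower = 1e-8, upper = 500, tol = 1e-12)$root
}

draw_ztp <- function(n, lambda) {
  k <- stats::rpois(n, lambda)
  while (any(zero <- k == 0L)) {
    k[zero] <- stats::rpois(sum(zero), lambda)
  }
  k
}

#' Generate a synthetic FAERS-like report set
#'
#' Draws reports under the configured generative model, assembles them
#' through the same path real files take ([assemble_reports()]), and returns
#' both the `report_set` (duplicates and missingness included; run
#' [deduplicate()] before analysis) and a ground-truth sidecar with the
#' injected associations and their closed-form expected contingency tables.
#'
#' @param config a [simulation_config()].
#' @return List of class `pv_simulation`: `reports` (a `report_set`),
#'   `tables` (the four raw FAERS-style tables), `truth` (ground-truth
#'   list).
#' @seealso [expected_table()], [recovery_experiment()],
#'   [write_faers_tables()]
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dn <- config$drugs$name
  p <- config$drugs$p_suspect
  K <- length(dn)
  ptv <- config$pts$pt
  w0 <- config$pts$weight
  npt <- length(ptv)

  lambda <- ztp_calibrate(config$mean_events_per_report, w0)
  mean_k <- lambda / (1 - exp(-lambda))

  # --- suspect drug draws (>= 1 per report via weighted fallback) ---
  sus <- matrix(stats::runif(n * K), nrow = n) <
    matrix(p, nrow = n, ncol = K, byrow = TRUE)
  none <- rowSums(sus) == 0L
  if (any(none)) {
    pick <- sample.int(K, sum(none), replace = TRUE, prob = p)
    sus[cbind(which(none), pick)] <- TRUE
  }

  pid <- as.character(1000000L + seq_len(n))
  cid <- as.character(5000000L + seq_len(n))

  # --- demographics ---
  start_d <- as.Date("2006-07-01"); end_d <- as.Date("2019-12-31")
  base_date <- start_d + sample.int(as.integer(end_d - start_d) + 1L, n,
                                    replace = TRUE) - 1L
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.653, 0.347))
  sex[stats::runif(n) < config$missingness["sex"]] <- "UNK"
  age <- pmin(pmax(round(stats::rnorm(n, 47, 17)), 0), 95)
  age_chr <- as.character(age)
  age_chr[stats::runif(n) < config$missingness["age"]] <- ""
  occp <- sample(c("MD", "PH", "OT", "LW", "CN"), n, replace = TRUE,
                 prob = c(0.38, 0.10, 0.35, 0.002, 0.168))
  occp[stats::runif(n) < config$missingness["reporter"]] <- ""

  # --- outcomes (independent flags, Table-1-like rates) ---
  oc_p <- c(DE = 0.0095, LT = 0.049, HO = 0.326, DS = 0.031, OT = 0.30)
  oc_rows <- lapply(names(oc_p), function(code) {
    hit <- stats::runif(n) < oc_p[[code]]
    data.frame(primaryid = pid[hit], outc_cod = code,
               stringsAsFactors = FALSE)
  })
  outc <- do.call(rbind, oc_rows)

  # --- drug rows ---
  idx <- which(sus, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  role <- ifelse(duplicated(idx[, 1L]), "SS", "PS")
  drug_rows <- data.frame(primaryid = pid[idx[, 1L]],
                          drugname = dn[idx[, 2L]],
                          role_cod = role, stringsAsFactors = FALSE)
  conc <- which(stats::runif(n) < config$concomitant_rate)
  if (length(conc)) {
    cd <- sample.int(K, length(conc), replace = TRUE)
    keep <- !sus[cbind(conc, cd)]
    if (any(keep)) {
      drug_rows <- rbind(drug_rows,
                         data.frame(primaryid = pid[conc[keep]],
                                    drugname = dn[cd[keep]],
                                    role_cod = "C",
                                    stringsAsFactors = FALSE))
    }
  }

  # --- reaction draws, stratified by exposure to associated drugs ---
  assoc <- config$associations
  k_ev <- draw_ztp(n, lambda)
  if (is.null(assoc) || nrow(assoc) == 0L) {
    strat <- rep(1L, n)
    strat_w <- list(w0)
  } else {
    adr <- unique(norm_term(assoc$drug))
    expo <- sus[, match(adr, norm_term(dn)), drop = FALSE]
    key <- as.integer(factor(apply(expo, 1L, paste, collapse = "")))
    strat <- key
    strat_w <- lapply(seq_len(max(key)), function(s) {
      row1 <- which(key == s)[1]
      w <- w0
      for (i in seq_len(nrow(assoc))) {
        di <- match(norm_term(assoc$drug[i]), norm_term(dn))
        if (sus[row1, di]) {
          pi_ <- match(norm_term(assoc$pt[i]), norm_term(ptv))
          w[pi_] <- w[pi_] * assoc$rr[i]
        }
      }
      w
    })
    # capped-probability warning: RR times the background per-report
    # inclusion probability cannot exceed one distinct occurrence
    for (i in seq_len(nrow(assoc))) {
      pi_ <- match(norm_term(assoc$pt[i]), norm_term(ptv))
      p_bg <- ztp_inclusion(lambda, w0[pi_] / sum(w0))
      if (assoc$rr[i] * p_bg > 1) {
        warning("association ", assoc$drug[i], " x ", assoc$pt[i],
                ": rr * background probability exceeds 1; ",
                "the effective per-report probability is capped",
                call. = FALSE)
      }
    }
  }
  reac_list <- vector("list", length(strat_w))
  for (s in seq_along(strat_w)) {
    rows <- which(strat == s)
    tot <- sum(k_ev[rows])
    if (tot == 0L) next
    draws <- sample.int(npt, tot, replace = TRUE,
                        prob = strat_w[[s]] / sum(strat_w[[s]]))
    reac_list[[s]] <- data.frame(
      primaryid = rep(pid[rows], k_ev[rows]),
      pt = ptv[draws], stringsAsFactors = FALSE)
  }
  reac <- do.call(rbind, reac_list)

  demo <- data.frame(primaryid = pid, caseid = cid,
                     fda_dt = format(base_date, "%Y%m%d"),
                     sex = sex, age = age_chr, age_cod = "YR",
                     occp_cod = occp, stringsAsFactors = FALSE)

  # --- duplicate case versions (same case, later FDA date, new id) ---
  dup <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup)) {
    dpid <- as.character(1000000L + n + seq_along(dup))
    ddemo <- demo[dup, , drop = FALSE]
    ddemo$primaryid <- dpid
    ddemo$fda_dt <- format(base_date[dup] +
                             sample.int(90L, length(dup), replace = TRUE),
                           "%Y%m%d")
    demo <- rbind(demo, ddemo)
    relabel <- function(tab) {
      sub <- tab[tab$primaryid %in% pid[dup], , drop = FALSE]
      sub$primaryid <- dpid[match(sub$primaryid, pid[dup])]
      rbind(tab, sub)
    }
    drug_rows <- relabel(drug_rows)
    reac <- relabel(reac)
    outc <- relabel(outc)
  }

  tables <- list(demo = demo, drug = drug_rows, reac = reac, outc = outc)
  reports <- assemble_reports(tables)
  reports <- add_provenance(reports, "generate_reports",
                            list(seed = config$seed, n_cases = n,
                                 n_duplicates = length(dup)))

  truth <- list(seed = config$seed, lambda = lambda,
                mean_events_target = config$mean_events_per_report,
                n_cases = n, n_duplicates = length(dup),
                drug_prevalence = stats::setNames(colMeans(sus), dn))
  if (!is.null(assoc) && nrow(assoc) > 0L) {
    truth$associations <- assoc
    truth$expected_tables <- lapply(seq_len(nrow(assoc)), function(i) {
      expected_table(config, assoc$drug[i], assoc$pt[i])
    })
  }
  structure(list(reports = reports, tables = tables, truth = truth),
            class = "pv_simulation")
}

#' @export
print.pv_simulation <- function(x, ...) {
  cat("<pv_simulation> seed", x$truth$seed, "\n")
  print(x$reports)
  invisible(x)
}

#' Write simulated tables in FAERS dialects
#'
#' Emits the four delimited tables in the requested dialect (round-trips
#' through [read_faers_tables()]) plus a `ground_truth.json` sidecar.
#'
#' @param sim a `pv_simulation` from [generate_reports()].
#' @param dir output directory (created if needed).
#' @param dialect `"dollar"` or `"comma"`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_faers_tables <- function(sim, dir, dialect = c("dollar", "comma")) {
  stopifnot(inherits(sim, "pv_simulation"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"),
             outc = file.path(dir, "outc.txt"))
  for (nm in names(paths)) {
    tab <- sim$tables[[nm]]
    if (dialect == "dollar") {
      utils::write.table(tab, paths[[nm]], sep = "$", quote = FALSE,
                         row.names = FALSE, na = "")
    } else {
      utils::write.csv(tab, paths[[nm]], row.names = FALSE, na = "")
    }
  }
  truth <- sim$truth
  truth$expected_tables <- lapply(truth$expected_tables, unclass)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, truth = file.path(dir, "ground_truth.json")))
}

#' Expected contingency table under the generative model
#'
#' Closed-form expected (report, PT) pair counts for a (drug, PT)
#' combination, without sampling: exposure strata over the associated drugs
#' are enumerated with their probabilities, and per-stratum PT inclusion
#' probabilities follow the zero-truncated Poisson draw model. Serves as the
#' recovery oracle: for rare drugs and events, the expected ROR approaches
#' the injected relative risk.
#'
#' The tiny coupling between drugs introduced by the at-least-one-drug
#' fallback draw is approximated as independence; cells scale linearly with
#' `n_reports`.
#'
#' @param config a [simulation_config()].
#' @param drug,pt names from the config vocabularies.
#' @return A `contingency_table` (fractional cells, pair unit).
#' @export
expected_table <- function(config, drug, pt) {
  stopifnot(inherits(config, "simulation_config"))
  dn <- norm_term(config$drugs$name)
  ptn <- norm_term(config$pts$pt)
  di <- match(norm_term(drug), dn)
  ti <- match(norm_term(pt), ptn)
  if (is.na(di)) stop2("expected_table: unknown drug '", drug, "'")
  if (is.na(ti)) stop2("expected_table: unknown PT '", pt, "'")
  p <- config$drugs$p_suspect
  w0 <- config$pts$weight
  lambda <- ztp_calibrate(config$mean_events_per_report, w0)

  # effective prevalence including the weighted fallback draw
  p0 <- prod(1 - p)
  p_eff <- p + p0 * p / sum(p)

  assoc <- config$associations
  if (is.null(assoc)) {
    assoc <- data.frame(drug = character(0), pt = character(0),
                        rr = numeric(0))
  }
  dstar <- union(unique(norm_term(assoc$drug)), dn[di])
  if (length(dstar) > 12L) {
    stop2("expected_table: too many associated drugs to enumerate")
  }
  patt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(dstar))))
  pe <- p_eff[match(dstar, dn)]
  a <- b <- c_ <- d <- 0
  for (r in seq_len(nrow(patt))) {
    s <- patt[r, ]
    prob <- prod(ifelse(s, pe, 1 - pe))
    if (prob == 0) next
    w <- w0
    for (i in seq_len(nrow(assoc))) {
      if (s[match(norm_term(assoc$drug[i]), dstar)]) {
        wi <- match(norm_term(assoc$pt[i]), ptn)
        w[wi] <- w[wi] * assoc$rr[i]
      }
    }
    incl <- ztp_inclusion(lambda, w / sum(w))
    n_here <- config$n_reports * prob
    if (s[match(dn[di], dstar)]) {
      a <- a + n_here * incl[ti]
      b <- b + n_here * (sum(incl) - incl[ti])
    } else {
      c_ <- c_ + n_here * incl[ti]
      d <- d + n_here * (sum(incl) - incl[ti])
    }
  }
  contingency_table(a, b, c_, d, unit = "pair",
                    drug = as.character(drug), term = as.character(pt),
                    level = "pt", integer_cells = FALSE)
}

#' Parameter-recovery experiment
#'
#' Runs generate -> deduplicate -> screen over independent replicates
#' (seeds `config$seed`, `config$seed + 1`, ...) and summarises, for each
#' injected association of the screened drug: the detection rate (combined
#' triple-positive), the mean estimated ROR, and the coverage of the ROR
#' 95\% CI over the injected relative risk. The fraction of
#' combined-positive terms per screen is also reported (the false-positive
#' rate under a null configuration).
#'
#' @param config a [simulation_config()].
#' @param replicates number of independent replicates (>= 1).
#' @param drug drug to screen; defaults to the first association's drug.
#' @param criteria a [signal_criteria()].
#' @return Object of class `recovery_result`: per-replicate data frame plus
#'   `detection_rate`, `mean_ror`, `ci_coverage`, `positive_term_rate`.
#' @export
recovery_experiment <- function(config, replicates, drug = NULL,
                                criteria = signal_criteria()) {
  stopifnot(inherits(config, "simulation_config"), is_count(replicates),
            replicates >= 1)
  assoc <- config$associations
  if (is.null(drug)) {
    if (is.null(assoc) || nrow(assoc) == 0L) {
      stop2("recovery_experiment: supply 'drug' when no association is ",
            "configured")
    }
    drug <- assoc$drug[1]
  }
  assoc_here <- if (!is.null(assoc)) {
    assoc[norm_term(assoc$drug) == norm_term(drug), , drop = FALSE]
  } else NULL
  rows <- list()
  pos_rate <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- generate_reports(cfg)
    rs <- deduplicate(sim$reports)
    sc <- run_screen(rs, drug_query(drug), level = "pt",
                     criteria = criteria)
    pos_rate[r] <- if (nrow(sc) > 0) mean(sc$combined_pos) else 0
    if (!is.null(assoc_here) && nrow(assoc_here) > 0L) {
      idx <- match(norm_term(assoc_here$pt), norm_term(sc$term))
      rows[[r]] <- data.frame(
        replicate = r, seed = cfg$seed,
        pt = assoc_here$pt, rr = assoc_here$rr,
        n = ifelse(is.na(idx), 0L, sc$n[idx]),
        ror = ifelse(is.na(idx), NA_real_, sc$ror[idx]),
        ci_low = ifelse(is.na(idx), NA_real_, sc$ror_ci_low[idx]),
        ci_high = ifelse(is.na(idx), NA_real_, sc$ror_ci_high[idx]),
        detected = ifelse(is.na(idx), FALSE, sc$combined_pos[idx]),
        stringsAsFactors = FALSE)
    }
  }
  per <- if (length(rows)) do.call(rbind, rows) else NULL
  out <- list(
    drug = drug, replicates = replicates, per_replicate = per,
    positive_term_rate = mean(pos_rate),
    detection_rate = if (!is.null(per)) mean(per$detected) else NA_real_,
    mean_ror = if (!is.null(per)) mean(per$ror, na.rm = TRUE) else NA_real_,
    ci_coverage = if (!is.null(per)) {
      mean(!is.na(per$ci_low) & per$ci_low <= per$rr &
             per$rr <= per$ci_high)
    } else NA_real_)
  class(out) <- "recovery_result"
  out
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>", x$drug, "x", x$replicates, "replicates\n")
  if (!is.null(x$per_replicate)) {
    cat(sprintf("  detection rate: %.3f; mean ROR: %.3f; CI coverage: %.3f\n",
                x$detection_rate, x$mean_ror, x$ci_coverage))
  }
  cat(sprintf("  combined-positive term rate: %.4f\n", x$positive_term_rate))
  invisible(x)
}
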