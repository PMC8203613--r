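# Disproportionality statistics on 2x2 contingency cells.
#
# Three classical measures are implemented: the reporting odds ratio (ROR)
# with its Wald 95% CI on the log scale, the proportional reporting ratio
# (PRR) with the Pearson chi-squared statistic, and the BCPNN information
# component (IC) with the closed-form Bayesian posterior approximation of
# its standard deviation. A signal is declared only when all three criteria
# are met simultaneously.

cells_of <- function(table) {
  if (inherits(table, "contingency_table")) {
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  } else if (is.numeric(table) && length(table) == 4L) {
    stats::setNames(as.numeric(table), c("a", "b", "c", "d"))
  } else {
    stop2("expected a contingency_table or a numeric vector (a, b, c, d)")
  }
}

# Vectorised engine over parallel cell vectors. Returns a data.frame with
# every statistic; the scalar user-facing wrappers and run_screen() both
# call this.
dispro_cells <- function(a, b, c, d,
                         correction = c("haldane-on-zero", "none"),
                         yates = FALSE,
                         orientation = c("row", "column")) {
  correction <- match.arg(correction)
  orientation <- match.arg(orientation)
  n <- a + b + c + d
  if (any(n <= 0)) stop2("N = a+b+c+d must be positive")

  # Haldane-Anscombe: add 0.5 to all four cells iff any cell is zero.
  # Applied to ROR/PRR/chi2 only; the Bayesian IC needs no correction.
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (correction == "none" && any(zero)) {
    stop2("zero cell with correction = \"none\": ",
          "ROR/PRR are undefined; use correction = \"haldane-on-zero\"")
  }
  k <- ifelse(zero, 0.5, 0)
  ac <- a + k; bc_ <- b + k; cc <- c + k; dc <- d + k
  nc <- ac + bc_ + cc + dc

  ror <- (ac * dc) / (bc_ * cc)
  se <- sqrt(1 / ac + 1 / bc_ + 1 / cc + 1 / dc)
  ci_low <- exp(log(ror) - 1.96 * se)
  ci_high <- exp(log(ror) + 1.96 * se)

  if (orientation == "row") {
    # Standard PRR: event rate among the drug's reports over the event rate
    # among all other drugs' reports.
    pm1 <- ac + bc_; pm2 <- cc + dc
    prr <- (ac / pm1) / (cc / pm2)
  } else {
    # Printed-variant orientation (column-wise margins).
    pm1 <- ac + cc; pm2 <- bc_ + dc
    prr <- (ac / pm1) / (bc_ / pm2)
  }
  if (any(pm1 <= 0)) stop2("PRR undefined: zero margin (first)")
  if (any(pm2 <= 0)) stop2("PRR undefined: zero margin (second)")

  num <- abs(ac * dc - bc_ * cc)
  if (isTRUE(yates)) num <- pmax(num - nc / 2, 0)
  chi2 <- nc * num^2 / ((ac + bc_) * (cc + dc) * (ac + cc) * (bc_ + dc))

  # BCPNN closed-form posterior approximation with the conventional priors
  # alpha1 = beta1 = gamma11 = 1, alpha = beta = 2.
  a1 <- 1; b1 <- 1; g11 <- 1; al <- 2; be <- 2
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + g) * (a + b + a1) * (a + c + b1)))
  ic_var <- (1 / log(2))^2 * (
    (n - a + g - g11) / ((a + g11) * (1 + n + g)) +
      (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
      (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be)))
  ic_sd <- sqrt(ic_var)
  point_ic <- ifelse(a > 0, log2(a * n / ((a + b) * (a + c))), -Inf)

  data.frame(a = a, b = b, c = c, d = d, n_total = n,
             ror = ror, ror_ci_low = ci_low, ror_ci_high = ci_high,
             corrected = zero,
             prr = prr, chi2 = chi2,
             ic = ic, ic_sd = ic_sd, ic_minus_2sd = ic - 2 * ic_sd,
             point_ic = point_ic)
}

#' Reporting odds ratio with Wald 95\% confidence interval
#'
#' `ROR = (a d)/(b c)`; `95% CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' With `correction = "haldane-on-zero"` (default), 0.5 is added to all four
#' cells if and only if any cell is zero; with `"none"`, a zero cell is an
#' error.
#'
#' @param table a [contingency_table()] or numeric `c(a, b, c, d)`.
#' @param correction `"haldane-on-zero"` or `"none"`.
#' @return Object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @examples
#' ror(c(10, 20, 30, 240))
#' @export
ror <- function(table, correction = c("haldane-on-zero", "none")) {
  z <- cells_of(table)
  r <- dispro_cells(z["a"], z["b"], z["c"], z["d"], correction = correction)
  structure(list(ror = r$ror, ci_low = r$ror_ci_low, ci_high = r$ror_ci_high,
                 corrected = r$corrected),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.2f (95%% CI %.2f-%.2f)%s\n", x$ror, x$ci_low, x$ci_high,
              if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' The default (row-wise) PRR compares the event's share among the target
#' drug's pairs with its share among all other drugs' pairs:
#' `PRR = (a/(a+b)) / (c/(c+d))`. `orientation = "column"` gives the
#' column-wise variant `(a/(a+c)) / (b/(b+d))` printed in some published
#' tables. The chi-squared statistic is Pearson's
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with Yates' continuity
#' replacement `(|ad - bc| - N/2)` (floored at 0) when `yates = TRUE`.
#'
#' @inheritParams ror
#' @param yates apply Yates' continuity correction to chi-squared.
#' @param orientation `"row"` (standard, default) or `"column"`.
#' @return Object of class `prr_result`: `prr`, `chi2`, `yates`,
#'   `orientation`.
#' @examples
#' prr_chi2(c(10, 20, 30, 240))
#' @export
prr_chi2 <- function(table, yates = FALSE,
                     orientation = c("row", "column"),
                     correction = c("haldane-on-zero", "none")) {
  z <- cells_of(table)
  r <- dispro_cells(z["a"], z["b"], z["c"], z["d"], correction = correction,
                    yates = yates, orientation = orientation)
  structure(list(prr = r$prr, chi2 = r$chi2, yates = isTRUE(yates),
                 orientation = match.arg(orientation),
                 corrected = r$corrected),
            class = "prr_result")
}

#' @export
print.prr_result <- function(x, ...) {
  cat(sprintf("PRR %.2f (chi2 %.2f%s)\n", x$prr, x$chi2,
              if (x$yates) ", Yates" else ""))
  invisible(x)
}

#' BCPNN information component
#'
#' The raw information component is
#' `point_ic = log2(a N / ((a+b)(a+c)))`, the log ratio of observed to
#' expected co-reporting under independence. The reported `ic` and `ic_sd`
#' come from the closed-form Bayesian posterior approximation (priors
#' `alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2`), which shrinks small
#' counts towards independence; the signal criterion uses
#' `ic_minus_2sd = ic - 2 ic_sd`. No continuity correction is needed:
#' `a = 0` gives `point_ic = -Inf` but a finite Bayesian `ic`.
#'
#' @inheritParams ror
#' @return Object of class `ic_result`: `ic`, `ic_sd`, `ic_minus_2sd`,
#'   `point_ic`.
#' @examples
#' bcpnn_ic(c(10, 20, 30, 240))
#' @export
bcpnn_ic <- function(table) {
  z <- cells_of(table)
  r <- dispro_cells(z["a"], z["b"], z["c"], z["d"])
  structure(list(ic = r$ic, ic_sd = r$ic_sd,
                 ic_minus_2sd = r$ic_minus_2sd, point_ic = r$point_ic),
            class = "ic_result")
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("IC %.2f (IC-2SD %.2f; point IC %.2f)\n",
              x$ic, x$ic_minus_2sd, x$point_ic))
  invisible(x)
}

#' Signal positivity criteria
#'
#' Default thresholds follow the standard triple rule: ROR 95\% CI lower
#' bound > 1 with N >= 3; PRR >= 2 with chi-squared >= 4 and N >= 3;
#' IC - 2SD > 0. `min_n` applies to all three: with fewer than `min_n`
#' target-event counts every flag is negative.
#'
#' @param min_n minimum target count `a` (default 3).
#' @param ror_ci_low ROR CI lower-bound threshold (exclusive, default 1).
#' @param prr_min PRR threshold (inclusive, default 2).
#' @param chi2_min chi-squared threshold (inclusive, default 4).
#' @param ic_minus_2sd_min IC-2SD threshold (exclusive, default 0).
#' @return Object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_n = 3, ror_ci_low = 1, prr_min = 2,
                            chi2_min = 4, ic_minus_2sd_min = 0) {
  if (!is_count(min_n) || min_n < 1) stop2("min_n must be a count >= 1")
  if (ror_ci_low <= 0 || prr_min <= 0 || chi2_min <= 0) {
    stop2("signal thresholds must be strictly positive")
  }
  structure(list(min_n = as.integer(min_n), ror_ci_low = ror_ci_low,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ic_minus_2sd_min = ic_minus_2sd_min),
            class = "signal_criteria")
}

#' @export
print.signal_criteria <- function(x, ...) {
  cat(sprintf(paste0("<signal_criteria> N >= %d; ROR CI low > %g; ",
                     "PRR >= %g & chi2 >= %g; IC-2SD > %g\n"),
              x$min_n, x$ror_ci_low, x$prr_min, x$chi2_min,
              x$ic_minus_2sd_min))
  invisible(x)
}

#' Combine the three statistics into a signal verdict
#'
#' A suspicious signal requires all three algorithms positive. With
#' `a < min_n` every flag is forced negative regardless of the statistics.
#'
#' @param ror_r a `ror_result`.
#' @param prr_r a `prr_result`.
#' @param ic_r an `ic_result`.
#' @param a the target cell count N (= a).
#' @param criteria a [signal_criteria()].
#' @return Object of class `signal_evaluation`: `n`, the three positivity
#'   flags, `combined_positive`, and the three statistics under
#'   `statistics`.
#' @export
evaluate_signal <- function(ror_r, prr_r, ic_r, a,
                            criteria = signal_criteria()) {
  stopifnot(inherits(ror_r, "ror_result"), inherits(prr_r, "prr_result"),
            inherits(ic_r, "ic_result"), inherits(criteria, "signal_criteria"))
  a <- unname(a)
  if (!is_count(a)) stop2("evaluate_signal: 'a' must be a nonnegative count")
  if (a < criteria$min_n) {
    rp <- pp <- ip <- FALSE
  } else {
    rp <- ror_r$ci_low > criteria$ror_ci_low
    pp <- prr_r$prr >= criteria$prr_min && prr_r$chi2 >= criteria$chi2_min
    ip <- ic_r$ic_minus_2sd > criteria$ic_minus_2sd_min
  }
  structure(list(n = as.integer(a), ror_positive = rp, prr_positive = pp,
                 ic_positive = ip, combined_positive = rp && pp && ip,
                 statistics = list(ror = ror_r, prr = prr_r, ic = ic_r),
                 criteria = criteria),
            class = "signal_evaluation")
}

#' @export
print.signal_evaluation <- function(x, ...) {
  mark <- function(p) if (p) "+" else "-"
  cat(sprintf("<signal_evaluation> N = %d; ROR%s PRR%s IC%s => %s\n",
              x$n, mark(x$ror_positive), mark(x$prr_positive),
              mark(x$ic_positive),
              if (x$combined_positive) "SIGNAL" else "no signal"))
  invisible(x)
}

#' Full disproportionality evaluation of one contingency table
#'
#' Convenience wrapper computing [ror()], [prr_chi2()] and [bcpnn_ic()] on
#' one table and combining them with [evaluate_signal()].
#'
#' @inheritParams ror
#' @inheritParams prr_chi2
#' @param criteria a [signal_criteria()].
#' @return Object of class `dispro_signal`; its `evaluation` element is the
#'   `signal_evaluation`, and `table` keeps the input cells.
#' @examples
#' dispro(contingency_table(10, 20, 30, 240))
#' @export
dispro <- function(table, criteria = signal_criteria(),
                   correction = c("haldane-on-zero", "none"),
                   yates = FALSE, orientation = c("row", "column")) {
  z <- cells_of(table)
  r <- ror(table, correction = correction)
  p <- prr_chi2(table, yates = yates, orientation = orientation,
                correction = correction)
  i <- bcpnn_ic(table)
  ev <- evaluate_signal(r, p, i, z["a"], criteria)
  structure(list(table = table, ror = r, prr = p, ic = i, evaluation = ev),
            class = "dispro_signal")
}

#' @export
print.dispro_signal <- function(x, ...) {
  z <- cells_of(x$table)
  cat(sprintf("N = %d | ROR %.2f (%.2f-%.2f) | PRR %.2f (%.2f) | IC %.2f (%.2f)\n",
              as.integer(z["a"]), x$ror$ror, x$ror$ci_low, x$ror$ci_high,
              x$prr$prr, x$prr$chi2, x$ic$ic, x$ic$ic_minus_2sd))
  print(x$evaluation)
  invisible(x)
}

#' @export
summary.dispro_signal <- function(object, ...) {
  print(object)
  invisible(object)
}
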