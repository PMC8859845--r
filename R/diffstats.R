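# Differential-frequency statistics between the target and control samples:
# per-year two-proportion chi-square tests, Benjamini-Hochberg FDR within
# each year, Fisher aggregation of a term's per-year p-values, and the log2
# frequency-ratio effect size with the zero-control sentinel.

#' Two-proportion chi-square test
#'
#' Tests equality of two binomial proportions via the Pearson chi-square
#' statistic on the explicit 2x2 table (1 df), with the Yates continuity
#' correction by default; the p-value is two-sided. A pooled proportion of
#' exactly 0 or 1 (no variation in the table) yields p = 1 with a
#' degenerate-table flag.
#'
#' @param x1,n1 Successes and size in the first group.
#' @param x2,n2 Successes and size in the second group.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return List with `statistic` (chi-square), `p.value`, `estimate`
#'   (the two proportions) and `degenerate`.
#' @examples
#' two_proportion_test(9, 10, 7, 10)$p.value    # not significant
#' two_proportion_test(90, 100, 70, 100)$p.value # significant
#' @export
two_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(n1 > 0L, n2 > 0L, x1 >= 0L, x2 >= 0L, x1 <= n1, x2 <= n2)
  est <- c(x1 / n1, x2 / n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(statistic = 0, p.value = 1, estimate = est,
                degenerate = TRUE))
  }
  O <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  dev <- abs(O - E)
  if (continuity) dev <- dev - pmin(0.5, dev)
  stat <- sum(dev^2 / E)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       estimate = est, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values,
#' preserving input order; adjusted values are capped at 1 and never smaller
#' than the raw values.
#'
#' @param pvalues Non-empty numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's method for combining p-values
#'
#' Aggregates k independent p-values as chi2 = -2 * sum(log(p)) referred to
#' a chi-square distribution with 2k degrees of freedom. Zero inputs are
#' clamped to the smallest positive double with a warning (log 0 is
#' undefined).
#'
#' @param pvalues Non-empty numeric vector in (0, 1\].
#' @return List with `statistic` (chi2), `df` (2k) and `p.value`.
#' @examples
#' fisher_aggregate(c(0.1, 0.1))  # chi2 = 9.21, df = 4
#' @export
fisher_aggregate <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(pvalues == 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Log2 frequency ratio with zero-control sentinel
#'
#' The effect size log2(target frequency / control frequency): positive
#' values mean the term is target-enriched, negative control-enriched, and
#' the absolute value gives the fold difference (|logratio| = 2 means a
#' four-fold difference). When the control frequency is zero the ratio is
#' undefined and the sentinel (default 10) is returned instead. Both
#' frequencies zero is an error (such terms are removed upstream by the
#' support filter).
#'
#' @param target_freq,control_freq Non-negative relative frequencies
#'   (vectors recycle).
#' @param sentinel Value returned when `control_freq` is 0; default 10.
#' @return Numeric vector of log ratios.
#' @examples
#' log_ratio(0.005, 0.020)  # -2: four times more frequent in control
#' log_ratio(0.004, 0)      # 10, the sentinel
#' @export
log_ratio <- function(target_freq, control_freq, sentinel = 10) {
  n <- max(length(target_freq), length(control_freq))
  tf <- rep_len(target_freq, n)
  cf <- rep_len(control_freq, n)
  if (any(tf < 0) || any(cf < 0)) stop("frequencies must be non-negative")
  if (any(tf == 0 & cf == 0)) {
    stop("log ratio undefined when both frequencies are zero")
  }
  ifelse(cf == 0, sentinel, log2(tf / cf))
}

# Per-year log ratio used inside compare_all_terms: NA where both counts
# are zero (no information that year) instead of an error.
log_ratio_cell <- function(tf, cf, sentinel = 10) {
  out <- rep(NA_real_, length(tf))
  ok <- !(tf == 0 & cf == 0)
  out[ok & cf == 0] <- sentinel
  both <- ok & cf > 0
  out[both] <- log2(tf[both] / cf[both])
  out
}

#' Differential-frequency analysis of every term in a panel
#'
#' For each term: a per-year two-proportion chi-square p-value over the
#' years where both samples have articles; BH adjustment across all terms
#' within each year (each year is one testing family); Fisher aggregation of
#' the term's raw per-year p-values; and a pooled log2 ratio from
#' whole-window relative frequencies (sum of counts / sum of sizes per
#' sample). `fisher_q` adds a BH adjustment of the aggregated p-values
#' across terms, used downstream as the default significance gate.
#'
#' @param panel A `freq_panel`, normally after support filtering.
#' @param continuity Yates correction for the per-year tests (default
#'   `TRUE`).
#' @param sentinel Zero-control sentinel passed to the log ratio.
#' @return A data.frame (one row per term) with columns `term`, `n_years`,
#'   `fisher_chi2`, `fisher_df`, `fisher_p`, `fisher_q`, `target_freq`,
#'   `control_freq`, `logratio`, `direction`; matrices of per-year raw and
#'   adjusted p-values and per-year log ratios are attached as attributes
#'   `per_year_p`, `per_year_q`, `per_year_logratio`.
#' @export
compare_all_terms <- function(panel, continuity = TRUE, sentinel = 10) {
  stopifnot(inherits(panel, "freq_panel"))
  years_use <- panel$years[panel$years_ok]
  if (length(years_use) == 0L) {
    stop("no year bin has articles in both samples")
  }
  ct <- panel$counts$target[, years_use, drop = FALSE]
  cc <- panel$counts$control[, years_use, drop = FALSE]
  nt <- panel$sizes$target[years_use]
  nc <- panel$sizes$control[years_use]

  keep <- rowSums(ct) + rowSums(cc) > 0L
  if (any(!keep)) {
    message(sum(!keep), " term(s) with no occurrences in any eligible ",
            "year excluded")
  }
  terms <- panel$terms[keep]
  ct <- ct[keep, , drop = FALSE]
  cc <- cc[keep, , drop = FALSE]

  P <- matrix(NA_real_, length(terms), length(years_use),
              dimnames = list(terms, years_use))
  for (j in seq_along(years_use)) {
    for (i in seq_along(terms)) {
      P[i, j] <- two_proportion_test(ct[i, j], nt[j], cc[i, j], nc[j],
                                     continuity = continuity)$p.value
    }
  }
  Q <- apply(P, 2L, bh_adjust)
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L, dimnames = dimnames(P))

  fisher <- t(vapply(seq_along(terms), function(i) {
    f <- fisher_aggregate(P[i, ])
    c(f$statistic, f$df, f$p.value)
  }, numeric(3L)))

  tfreq <- rowSums(ct) / sum(nt)
  cfreq <- rowSums(cc) / sum(nc)
  lr <- log_ratio(tfreq, cfreq, sentinel = sentinel)
  LR <- log_ratio_cell(as.numeric(sweep(ct, 2L, nt, "/")),
                       as.numeric(sweep(cc, 2L, nc, "/")), sentinel)
  LR <- matrix(LR, nrow = length(terms), dimnames = dimnames(P))

  out <- data.frame(
    term = terms,
    n_years = length(years_use),
    fisher_chi2 = fisher[, 1L],
    fisher_df = as.integer(fisher[, 2L]),
    fisher_p = fisher[, 3L],
    fisher_q = bh_adjust(fisher[, 3L]),
    target_freq = tfreq,
    control_freq = cfreq,
    logratio = lr,
    direction = ifelse(lr > 0, "target", ifelse(lr < 0, "control", "none")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "per_year_p") <- P
  attr(out, "per_year_q") <- Q
  attr(out, "per_year_logratio") <- LR
  out
}
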