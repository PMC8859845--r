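# Mann-Kendall monotone-trend testing on yearly frequency series, trend
# classification at a fixed p threshold, and frequency-change effect sizes.
#
# Series here are short (at most one point per year bin, typically <= 13),
# where the normal approximation to the null distribution of S is crude; an
# exact permutation version is provided for short series and used as the
# reference in validation.

#' Mann-Kendall trend test
#'
#' Computes S, the sum over all ordered pairs of the signs of forward
#' differences; its tie-corrected variance
#' \deqn{Var(S) = [n(n-1)(2n+5) - \sum_p t_p(t_p-1)(2t_p+5)]/18}
#' over tie groups of size \eqn{t_p}; the normal-approximation score z
#' (with a continuity correction of 1 toward zero by default, z = 0 when
#' S = 0); and the two-sided p-value. The test is rank-based: any strictly
#' monotone transform of the values leaves it unchanged. All values tied
#' gives S = 0, p = 1 and a degenerate flag.
#'
#' @param series Numeric vector (NA values are removed); at least 3
#'   observations required.
#' @param continuity Apply the continuity correction to z (default `TRUE`).
#' @return List with `S`, `varS`, `z`, `p.value`, `n` and `degenerate`.
#' @examples
#' mann_kendall(1:9)  # S = 36, varS = 92
#' @export
mann_kendall <- function(series, continuity = TRUE) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 3L) stop("Mann-Kendall test requires at least 3 observations")
  d <- sign(outer(x, x, "-"))       # d[i, j] = sign(x[i] - x[j])
  S <- sum(d[lower.tri(d)])         # rows > cols: later minus earlier
  tie_sizes <- table(x)
  tie_sizes <- tie_sizes[tie_sizes > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
           sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  if (varS <= 0) {
    return(list(S = S, varS = 0, z = 0, p.value = 1, n = n,
                degenerate = TRUE))
  }
  shift <- if (continuity) 1 else 0
  z <- if (S > 0) (S - shift) / sqrt(varS)
       else if (S < 0) (S + shift) / sqrt(varS)
       else 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(S = S, varS = varS, z = z, p.value = p, n = n, degenerate = FALSE)
}

# All permutations of 1..n as an n!-row matrix (n <= 8).
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[r <- r + 1L, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Exact permutation Mann-Kendall test
#'
#' Enumerates all n! orderings of the observed values and returns the exact
#' two-sided p-value P(|S| >= |S_obs|) under the null of exchangeability.
#' Practical for n <= 8.
#'
#' @param series Numeric vector (NA removed), 3 <= n <= 8.
#' @return List with `S`, `p.value` and `n`.
#' @export
mann_kendall_exact <- function(series) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 3L) stop("Mann-Kendall test requires at least 3 observations")
  if (n > 8L) stop("exact permutation test supported only for n <= 8")
  D <- -sign(outer(x, x, "-"))      # D[a, b] = sign(x[b] - x[a])
  upper <- upper.tri(D)
  s_of <- function(o) sum(D[o, o][upper])
  S_obs <- s_of(seq_len(n))
  perms <- perm_matrix(n)
  S_all <- vapply(seq_len(nrow(perms)),
                  function(r) s_of(perms[r, ]), numeric(1L))
  list(S = S_obs, p.value = mean(abs(S_all) >= abs(S_obs)), n = n)
}

#' Classify a trend at a significance threshold
#'
#' `"up"` when p <= threshold and S > 0, `"down"` when p <= threshold and
#' S < 0, `"none"` otherwise. The default threshold is 0.01 and no
#' multiple-testing correction is applied across terms, reflecting the
#' limited power of the test on short yearly series.
#'
#' @param p,S Vectors of Mann-Kendall p-values and S statistics (recycled).
#' @param threshold Significance threshold in (0, 1); default 0.01.
#' @return Character vector in `c("up", "down", "none")`.
#' @export
classify_trend <- function(p, S, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(p <= threshold & S > 0, "up",
         ifelse(p <= threshold & S < 0, "down", "none"))
}

#' Sen's slope
#'
#' Median of all pairwise slopes (x_j - x_i)/(j - i); a robust companion
#' effect size to the Mann-Kendall test.
#'
#' @param series Numeric vector of at least 2 values, one per time step.
#' @return Scalar slope per time step.
#' @export
sen_slope <- function(series) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 2L) stop("Sen's slope requires at least 2 observations")
  ij <- utils::combn(n, 2L)
  stats::median((x[ij[2L, ]] - x[ij[1L, ]]) / (ij[2L, ] - ij[1L, ]))
}

#' Endpoint frequency change in percentage points
#'
#' (last - first) x 100 over the observed series, e.g. a share falling from
#' 0.79 to 0.45 is a change of -34 percentage points.
#'
#' @param series Relative-frequency series of at least 2 values.
#' @return Scalar change in percentage points.
#' @export
frequency_delta <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) stop("frequency delta requires at least 2 observations")
  (x[length(x)] - x[1L]) * 100
}

#' Trend scan over a frequency panel
#'
#' Runs the Mann-Kendall test on the yearly relative-frequency series of
#' every trend-eligible (term, sample) pair (see [filter_min_years()]),
#' classifies each at `threshold`, and reports both the endpoint change in
#' percentage points and Sen's slope. Year bins with no articles in the
#' sample are removed from a series, not imputed as zeros. The trend is
#' computed within each sample separately and both samples are reported.
#'
#' @param panel A `freq_panel`; if eligibility flags are absent,
#'   [filter_min_years()] is applied with its default.
#' @param threshold Classification threshold on the Mann-Kendall p-value;
#'   default 0.01.
#' @param continuity Continuity correction for the normal approximation.
#' @return A data.frame with one row per eligible (term, sample): `term`,
#'   `sample`, `n_years`, `S`, `varS`, `z`, `p`, `direction`, `delta_pp`,
#'   `sen_slope`; a per-sample up/down/none summary is attached as
#'   attribute `summary`.
#' @export
trend_scan <- function(panel, threshold = 0.01, continuity = TRUE) {
  stopifnot(inherits(panel, "freq_panel"))
  if (is.null(panel$trend_eligible)) panel <- filter_min_years(panel)
  rows <- list()
  for (s in c("target", "control")) {
    ok_years <- panel$sizes[[s]] > 0L
    rf <- relfreq(panel, s)[, ok_years, drop = FALSE]
    for (term in panel$terms[panel$trend_eligible[[s]][panel$terms]]) {
      series <- rf[term, ]
      mk <- mann_kendall(series, continuity = continuity)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, sample = s, n_years = mk$n,
        S = mk$S, varS = mk$varS, z = mk$z, p = mk$p.value,
        direction = classify_trend(mk$p.value, mk$S, threshold),
        delta_pp = frequency_delta(series),
        sen_slope = sen_slope(series),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    warning("no (term, sample) series is trend-eligible")
    out <- data.frame(term = character(), sample = character(),
                      n_years = integer(), S = numeric(), varS = numeric(),
                      z = numeric(), p = numeric(), direction = character(),
                      delta_pp = numeric(), sen_slope = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  attr(out, "summary") <- if (nrow(out) > 0L) {
    table(sample = out$sample,
          direction = factor(out$direction, c("up", "down", "none")))
  } else {
    NULL
  }
  attr(out, "threshold") <- threshold
  out
}
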