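# Per-term, per-year, per-sample frequency panels and the support filters.
#
# A panel stores raw counts (articles in sample s, bin y, carrying term t)
# and per-bin sample sizes; relative frequencies are always computed from
# these at use time as exact ratios, never pre-rounded.

count_matrix <- function(articles, terms, year_levels) {
  tl <- articles$terms
  yr <- rep(as.character(articles$year_bin), lengths(tl))
  tm <- unlist(tl, use.names = FALSE)
  tab <- table(factor(tm, levels = terms), factor(yr, levels = year_levels))
  matrix(as.integer(tab), nrow = length(terms),
         dimnames = list(terms, year_levels))
}

#' Build a term x year x sample frequency panel
#'
#' Counts, for every MeSH term observed in either sample, the number of
#' articles per year bin whose term set contains it; the relative frequency
#' of a term is its count divided by the bin's sample size (see
#' [relfreq()]). Terms absent in a year have count zero. Year bins that are
#' empty in either sample are flagged and excluded from per-year tests
#' downstream.
#'
#' @param target,control `sample_corpus` objects sharing one year-bin
#'   sequence (see [build_samples()]).
#' @return A `freq_panel`: list with `terms`, `years`, `counts` (list of two
#'   term-by-year integer matrices), `sizes` (list of two named integer
#'   vectors), `years_ok` (logical: positive size in both samples) and a
#'   `log` of filter bookkeeping.
#' @export
build_panel <- function(target, control) {
  stopifnot(inherits(target, "sample_corpus"),
            inherits(control, "sample_corpus"))
  if (!identical(names(target$year_sizes), names(control$year_sizes))) {
    stop("target and control corpora use different year-bin sequences")
  }
  years <- names(target$year_sizes)
  terms <- sort(unique(c(unlist(target$articles$terms, use.names = FALSE),
                         unlist(control$articles$terms, use.names = FALSE))))
  if (length(terms) == 0L) stop("no MeSH terms observed in either sample")
  sizes <- list(target = target$year_sizes, control = control$year_sizes)
  years_ok <- sizes$target > 0L & sizes$control > 0L
  if (any(!years_ok)) {
    message("year bin(s) empty in at least one sample, excluded from ",
            "per-year tests: ", paste(years[!years_ok], collapse = ", "))
  }
  structure(
    list(terms = terms, years = years,
         counts = list(target = count_matrix(target$articles, terms, years),
                       control = count_matrix(control$articles, terms, years)),
         sizes = sizes,
         years_ok = stats::setNames(as.logical(years_ok), years),
         trend_eligible = NULL,
         log = list()),
    class = "freq_panel"
  )
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("<freq_panel> ", length(x$terms), " terms x ", length(x$years),
      " year bins; sizes target=", sum(x$sizes$target), ", control=",
      sum(x$sizes$control), "\n", sep = "")
  invisible(x)
}

#' Relative frequencies for one sample
#'
#' @param panel A `freq_panel`.
#' @param sample `"target"` or `"control"`.
#' @return Term-by-year matrix of counts/sizes; columns with size zero are
#'   `NaN`.
#' @export
relfreq <- function(panel, sample = c("target", "control")) {
  sample <- match.arg(sample)
  sweep(panel$counts[[sample]], 2L, panel$sizes[[sample]], "/")
}

subset_panel <- function(panel, keep_terms) {
  panel$counts <- lapply(panel$counts, function(m) m[keep_terms, , drop = FALSE])
  panel$terms <- panel$terms[panel$terms %in% keep_terms]
  if (!is.null(panel$trend_eligible)) {
    panel$trend_eligible <- lapply(panel$trend_eligible,
                                   function(v) v[panel$terms])
  }
  panel
}

#' Restrict a panel to MeSH categories
#'
#' Drops terms that are not mapped by the vocabulary or whose category set
#' does not intersect `allowed`. Unmapped and out-of-category removals are
#' tallied separately in the panel log. With `allowed = NULL` the panel is
#' returned unchanged (filtering disabled).
#'
#' @param panel A `freq_panel`.
#' @param vocab A `mesh_vocabulary`.
#' @param allowed Category letters, default `c("C", "D", "E")`.
#' @return The filtered panel.
#' @export
filter_categories <- function(panel, vocab, allowed = c("C", "D", "E")) {
  stopifnot(inherits(panel, "freq_panel"))
  if (is.null(allowed)) return(panel)
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  desc <- vocab_lookup(vocab, panel$terms)
  mapped <- !vapply(desc, is.null, logical(1L))
  inside <- mapped
  inside[mapped] <- vapply(desc[mapped],
                           function(d) in_categories(d, allowed), logical(1L))
  keep <- panel$terms[inside]
  if (length(keep) == 0L) stop("no terms survive the category filter")
  out <- subset_panel(panel, keep)
  out$log$category <- list(
    allowed = allowed,
    n_unmapped = sum(!mapped),
    n_out_of_category = sum(mapped & !inside),
    removed = panel$terms[!inside]
  )
  if (sum(!mapped) > 0L) {
    message(sum(!mapped), " term(s) absent from the vocabulary dropped ",
            "under category filtering")
  }
  out
}

#' Remove low-support terms
#'
#' A term is retained only when it is associated with more than `threshold`
#' articles in the target sample AND more than `threshold` in the control
#' sample, summed over the whole window (with the default 5, terms with five
#' or fewer papers in either sample are removed). The per-sample rule
#' follows the rule-of-five motivation for the chi-square test: every
#' comparison should rest on adequately supported cells on both sides.
#'
#' @param panel A `freq_panel`.
#' @param threshold Non-negative integer; default 5.
#' @return The filtered panel; removal bookkeeping in `panel$log$support`.
#' @export
filter_min_support <- function(panel, threshold = 5L) {
  stopifnot(inherits(panel, "freq_panel"), threshold >= 0L)
  tot_t <- rowSums(panel$counts$target)
  tot_c <- rowSums(panel$counts$control)
  keep_mask <- tot_t > threshold & tot_c > threshold
  keep <- panel$terms[keep_mask]
  if (length(keep) == 0L) stop("no terms survive support filter")
  out <- subset_panel(panel, keep)
  out$log$support <- list(threshold = threshold,
                          n_removed = sum(!keep_mask),
                          removed = panel$terms[!keep_mask])
  out
}

#' Flag terms eligible for trend analysis
#'
#' A (term, sample) series is trend-eligible iff the term has a non-zero
#' count in at least `min_years` distinct year bins in that sample
#' ("occurrence data available"): series observed in fewer years are
#' excluded from the trend test, not imputed.
#'
#' @param panel A `freq_panel`.
#' @param min_years Minimum number of observed years; default 6.
#' @return The panel with a `trend_eligible` list (one named logical vector
#'   per sample).
#' @export
filter_min_years <- function(panel, min_years = 6L) {
  stopifnot(inherits(panel, "freq_panel"))
  if (min_years > length(panel$years)) {
    stop("min_years exceeds the number of year bins")
  }
  panel$trend_eligible <- lapply(panel$counts, function(m) {
    stats::setNames(rowSums(m > 0L) >= min_years, rownames(m))
  })
  panel$log$min_years <- list(
    min_years = min_years,
    n_ineligible = vapply(panel$trend_eligible,
                          function(v) sum(!v), integer(1L))
  )
  panel
}

#' Normalize yearly sample sizes to database-wide totals
#'
#' Expresses each year's sample size as a share of the whole database's
#' article output that year (the normalization used to compare sample growth
#' against overall literature growth).
#'
#' @param year_sizes Named integer vector (year -> sample size).
#' @param db_totals Named positive integer vector covering every year in
#'   `year_sizes`.
#' @return Named numeric vector of shares.
#' @export
normalize_to_database_totals <- function(year_sizes, db_totals) {
  missing_years <- setdiff(names(year_sizes), names(db_totals))
  if (length(missing_years) > 0L) {
    stop("db_totals missing year(s): ", paste(missing_years, collapse = ", "))
  }
  tot <- db_totals[names(year_sizes)]
  if (any(tot <= 0)) {
    stop("db_totals must be positive for every year")
  }
  year_sizes / tot
}

#' Export a panel as a long-format table
#'
#' @param x A `freq_panel`.
#' @param ... Unused.
#' @return data.frame with columns sample, term, year, count, size, relfreq.
#' @export
as.data.frame.freq_panel <- function(x, ...) {
  blocks <- lapply(c("target", "control"), function(s) {
    m <- x$counts[[s]]
    data.frame(
      sample = s,
      term = rep(rownames(m), times = ncol(m)),
      year = rep(colnames(m), each = nrow(m)),
      count = as.integer(m),
      size = rep(x$sizes[[s]], each = nrow(m)),
      relfreq = as.numeric(sweep(m, 2L, x$sizes[[s]], "/")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}
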