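# Article input, sample assembly and yearly binning.
#
# Articles enter either as MEDLINE/PubMed XML (PubmedArticleSet /
# MedlineCitation / MeshHeadingList) or as a plain TSV interchange format:
#   pmid <TAB> date-or-year <TAB> semicolon-joined MeSH descriptor names
# Only descriptor names are counted; qualifiers (subheadings) attached to a
# heading are ignored, i.e. counting is descriptor-only.

# Build the canonical article data.frame (pmid, date, terms list-column).
articles_frame <- function(pmid, date, terms) {
  df <- data.frame(pmid = as.integer(pmid), date = as.Date(date))
  df$terms <- terms
  df
}

parse_article_date <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  is_year <- grepl("^[0-9]{4}$", x)
  if (any(is_year)) {
    out[is_year] <- as.Date(paste0(x[is_year], "-01-01"))
  }
  rest <- which(!is_year & nzchar(x))
  if (length(rest) > 0L) {
    d <- as.Date(x[rest], format = "%Y-%m-%d")
    d2 <- as.Date(x[rest], format = "%Y/%m/%d")
    d[is.na(d)] <- d2[is.na(d)]
    out[rest] <- d
  }
  out
}

split_terms <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(t) {
    t <- trimws(t)
    unique(t[nzchar(t)])
  })
}

#' Read article records
#'
#' One `Article` per record: a PMID, a publication date (a bare year is
#' taken as January 1 of that year) and the set of MeSH descriptor names.
#' Records lacking any MeSH term are retained with an empty term set; they
#' contribute to sample sizes but to no term count. Duplicate descriptor
#' names within a record are deduplicated. Unparseable records (bad PMID or
#' date) are skipped with a warning reporting the skipped count; a file with
#' zero parseable records is an error.
#'
#' @param path File path.
#' @param format `"tsv"` (pmid, date-or-year, semicolon-joined names) or
#'   `"medline-xml"` (`PubmedArticleSet`/`MedlineCitation` dialect).
#' @return A data.frame with columns `pmid` (integer), `date` (Date) and a
#'   list-column `terms` (character sets).
#' @export
read_articles <- function(path, format = c("tsv", "medline-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("article file not found: ", path)
  switch(format,
    tsv            = read_articles_tsv(path),
    `medline-xml`  = read_articles_xml(path)
  )
}

read_articles_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  n <- length(lines)
  pmid <- rep(NA_integer_, n)
  date <- rep(as.Date(NA), n)
  term_field <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) next
    pmid[i] <- suppressWarnings(as.integer(trimws(fields[[1L]])))
    date[i] <- parse_article_date(fields[[2L]])
    term_field[i] <- if (length(fields) >= 3L) fields[[3L]] else ""
  }
  ok <- !is.na(pmid) & pmid > 0L & !is.na(date)
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    warning("skipped ", n_skip, " unparseable article record(s) in '",
            path, "'")
  }
  if (!any(ok)) stop("no parseable article records in '", path, "'")
  articles_frame(pmid[ok], date[ok], split_terms(term_field[ok]))
}

month_to_num <- function(m) {
  m <- trimws(m)
  num <- suppressWarnings(as.integer(m))
  abbr <- match(tolower(substr(m, 1L, 3L)), tolower(month.abb))
  ifelse(!is.na(num), num, abbr)
}

read_articles_xml <- function(path) {
  doc <- xml2::read_xml(path)
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(cits) == 0L) stop("no article records in '", path, "'")
  pmid <- rep(NA_integer_, length(cits))
  date <- rep(as.Date(NA), length(cits))
  terms <- vector("list", length(cits))
  for (i in seq_along(cits)) {
    cit <- cits[[i]]
    pmid[i] <- suppressWarnings(as.integer(
      xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))))
    pd <- xml2::xml_find_first(cit, ".//Journal/JournalIssue/PubDate")
    yr <- xml2::xml_text(xml2::xml_find_first(pd, "./Year"))
    if (is.na(yr)) {
      # MedlineDate fallback, e.g. "2016 Nov-Dec"
      md <- xml2::xml_text(xml2::xml_find_first(pd, "./MedlineDate"))
      yr <- regmatches(md, regexpr("[0-9]{4}", md))
      if (length(yr) == 0L) yr <- NA_character_
    }
    if (!is.na(yr)) {
      mo <- month_to_num(xml2::xml_text(xml2::xml_find_first(pd, "./Month")))
      dy <- suppressWarnings(as.integer(
        xml2::xml_text(xml2::xml_find_first(pd, "./Day"))))
      if (is.na(mo)) mo <- 1L
      if (is.na(dy)) dy <- 1L
      date[i] <- suppressWarnings(
        as.Date(sprintf("%s-%02d-%02d", yr, mo, dy)))
    }
    tm <- xml2::xml_text(xml2::xml_find_all(
      cit, "./MeshHeadingList/MeshHeading/DescriptorName"))
    terms[[i]] <- unique(trimws(tm))
  }
  ok <- !is.na(pmid) & pmid > 0L & !is.na(date)
  n_skip <- sum(!ok)
  if (n_skip > 0L) {
    warning("skipped ", n_skip, " unparseable article record(s) in '",
            path, "'")
  }
  if (!any(ok)) stop("no parseable article records in '", path, "'")
  articles_frame(pmid[ok], date[ok], terms[ok])
}

#' Calendar-year binning intervals
#'
#' @param years Integer vector of calendar years.
#' @return A data.frame with columns `start`, `end` (Dates, both closed) and
#'   `label`, one row per year.
#' @export
year_intervals <- function(years) {
  years <- sort(unique(as.integer(years)))
  data.frame(start = as.Date(paste0(years, "-01-01")),
             end   = as.Date(paste0(years, "-12-31")),
             label = as.character(years),
             stringsAsFactors = FALSE)
}

#' PubMed publication-date window intervals
#'
#' Yearly windows running from a fixed month-day boundary to the day before
#' the same boundary one year later (the closed `[PDat]` range convention),
#' e.g. Oct 22 of year Y through Oct 21 of year Y+1.
#'
#' @param start_years Integer vector: the year each window opens in.
#' @param boundary `"MM-DD"` month-day at which windows start.
#' @return Interval data.frame as in [year_intervals()]; labels are
#'   `"Y-Y+1"`.
#' @export
pdat_intervals <- function(start_years, boundary = "10-22") {
  start_years <- sort(unique(as.integer(start_years)))
  start <- as.Date(paste0(start_years, "-", boundary))
  end <- as.Date(paste0(start_years + 1L, "-", boundary)) - 1L
  data.frame(start = start, end = end,
             label = paste0(start_years, "-", start_years + 1L),
             stringsAsFactors = FALSE)
}

#' Assign articles to yearly intervals
#'
#' Each article is assigned to the unique interval whose closed `[start,
#' end]` range contains its publication date. Articles outside all intervals
#' are dropped with a logged count. Overlapping or unordered intervals are a
#' configuration error.
#'
#' @param articles Article data.frame from [read_articles()].
#' @param intervals Interval data.frame ([year_intervals()] /
#'   [pdat_intervals()]).
#' @return `articles` restricted to the covered dates, with a `year_bin`
#'   factor column whose levels are the interval labels in order.
#' @export
bin_by_year <- function(articles, intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "label") %in% names(intervals)))
  if (nrow(intervals) == 0L) stop("configuration error: no intervals")
  if (any(intervals$end < intervals$start)) {
    stop("configuration error: interval end precedes start")
  }
  if (is.unsorted(intervals$start, strictly = TRUE)) {
    stop("configuration error: intervals must be ordered by start date")
  }
  n <- nrow(intervals)
  if (n > 1L && any(intervals$start[-1L] <= intervals$end[-n])) {
    stop("configuration error: overlapping intervals")
  }
  idx <- rep(NA_integer_, nrow(articles))
  for (k in seq_len(n)) {
    hit <- articles$date >= intervals$start[k] & articles$date <= intervals$end[k]
    idx[hit] <- k
  }
  dropped <- sum(is.na(idx))
  if (dropped > 0L) {
    message(dropped, " article(s) outside all intervals dropped")
  }
  out <- articles[!is.na(idx), , drop = FALSE]
  out$year_bin <- factor(intervals$label[idx[!is.na(idx)]],
                         levels = intervals$label)
  attr(out, "n_outside") <- dropped
  out
}

new_sample_corpus <- function(label, articles) {
  sizes <- table(articles$year_bin)
  structure(
    list(label = label, articles = articles,
         year_sizes = stats::setNames(as.integer(sizes), names(sizes))),
    class = "sample_corpus"
  )
}

#' @export
print.sample_corpus <- function(x, ...) {
  cat("<sample_corpus> '", x$label, "': ", nrow(x$articles),
      " articles in ", length(x$year_sizes), " year bin(s)\n", sep = "")
  invisible(x)
}

#' Assemble disjoint target and control samples
#'
#' PMIDs occurring in both input collections are excluded from both samples,
#' so every retained article is uniquely attributed to target or control.
#' Per-bin sample sizes are recomputed after the exclusion. Duplicate PMIDs
#' within one input are collapsed to their first occurrence with a warning.
#'
#' @param target_articles,control_articles Binned article data.frames (see
#'   [bin_by_year()]); both must carry the same `year_bin` levels.
#' @return A list with elements `target` and `control` (each a
#'   `sample_corpus` with fields `label`, `articles`, `year_sizes` and
#'   `n_removed_shared`) and `shared_pmids`.
#' @export
build_samples <- function(target_articles, control_articles) {
  for (nm in list(target_articles, control_articles)) {
    if (!"year_bin" %in% names(nm)) {
      stop("articles must be binned with bin_by_year() before build_samples()")
    }
  }
  if (!identical(levels(target_articles$year_bin),
                 levels(control_articles$year_bin))) {
    stop("target and control use different year-bin sequences")
  }
  if (nrow(target_articles) == 0L || nrow(control_articles) == 0L) {
    stop("both samples must be non-empty")
  }
  dedup_within <- function(df, label) {
    if (anyDuplicated(df$pmid)) {
      warning("duplicate PMIDs within the ", label,
              " sample collapsed to first occurrence")
      df <- df[!duplicated(df$pmid), , drop = FALSE]
    }
    df
  }
  target_articles <- dedup_within(target_articles, "target")
  control_articles <- dedup_within(control_articles, "control")
  shared <- intersect(target_articles$pmid, control_articles$pmid)
  tkeep <- target_articles[!target_articles$pmid %in% shared, , drop = FALSE]
  ckeep <- control_articles[!control_articles$pmid %in% shared, , drop = FALSE]
  if (nrow(tkeep) == 0L && nrow(ckeep) == 0L) {
    stop("samples fully overlap: every PMID occurs in both inputs")
  }
  if (nrow(tkeep) == 0L || nrow(ckeep) == 0L) {
    stop("sample '", if (nrow(tkeep) == 0L) "target" else "control",
         "' is empty after removing shared PMIDs")
  }
  tgt <- new_sample_corpus("target", tkeep)
  ctl <- new_sample_corpus("control", ckeep)
  tgt$n_removed_shared <- length(shared)
  ctl$n_removed_shared <- length(shared)
  list(target = tgt, control = ctl, shared_pmids = shared)
}
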