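# End-to-end pipeline driver and presentation-layer exports: result tables,
# wordcloud weight tables, heatmap matrices, corpus summary statistics and
# a machine-readable run manifest with full filter bookkeeping.

#' Configure a pipeline run
#'
#' Every defaulted parameter equals the method's stated value: categories
#' C/D/E, support threshold 5 (five or fewer papers removed, per sample),
#' minimum 6 observed years for trend eligibility, Mann-Kendall threshold
#' 0.01, Yates-corrected proportion tests.
#'
#' @param target,control Article inputs: file paths (TSV or MEDLINE XML by
#'   extension) or article data.frames as from [read_articles()].
#' @param vocabulary Optional `mesh_vocabulary` or vocabulary file path;
#'   required when `categories` is non-NULL.
#' @param intervals Optional interval data.frame; default is calendar-year
#'   bins spanning the input dates.
#' @param categories Category whitelist (default `c("C","D","E")`); `NULL`
#'   disables category filtering.
#' @param support_threshold Whole-window per-sample support threshold.
#' @param min_years Minimum observed years for trend eligibility.
#' @param trend_threshold Mann-Kendall classification threshold.
#' @param continuity Yates correction for the per-year proportion tests.
#' @param diff_alpha Significance gate on `fisher_q` used by
#'   [wordcloud_table()].
#' @param sentinel Zero-control log-ratio sentinel.
#' @param db_totals Optional named vector of database-wide per-year article
#'   totals for [normalize_to_database_totals()].
#' @param out_dir Optional output directory for CSV tables and the JSON
#'   manifest.
#' @return A validated `run_config`.
#' @export
run_config <- function(target, control, vocabulary = NULL,
                       intervals = NULL, categories = c("C", "D", "E"),
                       support_threshold = 5L, min_years = 6L,
                       trend_threshold = 0.01, continuity = TRUE,
                       diff_alpha = 0.05, sentinel = 10,
                       db_totals = NULL, out_dir = NULL) {
  if (!is.null(categories)) {
    if (length(categories) == 0L || !all(grepl("^[A-Z]$", categories))) {
      stop("validation error: categories must be single uppercase letters")
    }
    if (is.null(vocabulary)) {
      stop("validation error: category filtering requires a vocabulary")
    }
  }
  stopifnot(support_threshold >= 0L, min_years >= 0L,
            trend_threshold > 0, trend_threshold < 1,
            diff_alpha > 0, diff_alpha <= 1)
  structure(
    list(target = target, control = control, vocabulary = vocabulary,
         intervals = intervals, categories = categories,
         support_threshold = as.integer(support_threshold),
         min_years = as.integer(min_years),
         trend_threshold = trend_threshold, continuity = continuity,
         diff_alpha = diff_alpha, sentinel = sentinel,
         db_totals = db_totals, out_dir = out_dir),
    class = "run_config"
  )
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

resolve_articles <- function(x, what) {
  if (is.character(x)) {
    fmt <- if (grepl("\\.xml$", x, ignore.case = TRUE)) "medline-xml" else "tsv"
    list(articles = read_articles(x, format = fmt), path = x)
  } else if (is.data.frame(x)) {
    list(articles = x, path = NULL)
  } else {
    stop("validation error: '", what,
         "' must be a file path or an article data.frame")
  }
}

resolve_vocabulary <- function(x) {
  if (is.null(x)) return(list(vocab = NULL, path = NULL))
  if (is.character(x)) {
    fmt <- if (grepl("\\.xml$", x, ignore.case = TRUE)) "mesh-xml" else "tsv"
    list(vocab = load_vocabulary(x, format = fmt), path = x)
  } else if (inherits(x, "mesh_vocabulary")) {
    list(vocab = x, path = NULL)
  } else {
    stop("validation error: 'vocabulary' must be a path or mesh_vocabulary")
  }
}

#' Run the full comparison pipeline
#'
#' Executes corpus assembly (shared-PMID exclusion, yearly binning), panel
#' construction, category and support filtering, trend-eligibility
#' flagging, the differential-frequency analysis and the trend scan, and
#' assembles a manifest recording the configuration, input hashes and the
#' article/term counts removed at every filter stage. When `out_dir` is set
#' the result tables (long panel, comparisons, trends, per-sample
#' summaries) and the manifest are written there; partially written
#' outputs are removed if a stage fails.
#'
#' @param config A [run_config()].
#' @return A `meshtrends_run`: list with `panel`, `comparisons`, `trends`,
#'   `summary` (per sample), `db_shares` (when `db_totals` given),
#'   `manifest` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  tgt_in <- with_stage("corpus_io", resolve_articles(config$target, "target"))
  ctl_in <- with_stage("corpus_io", resolve_articles(config$control, "control"))
  voc_in <- with_stage("mesh_vocab", resolve_vocabulary(config$vocabulary))

  intervals <- config$intervals
  if (is.null(intervals)) {
    yrs <- as.integer(format(c(tgt_in$articles$date, ctl_in$articles$date),
                             "%Y"))
    intervals <- year_intervals(seq(min(yrs), max(yrs)))
  }
  n_read <- c(target = nrow(tgt_in$articles), control = nrow(ctl_in$articles))
  tgt_bin <- with_stage("corpus_io", bin_by_year(tgt_in$articles, intervals))
  ctl_bin <- with_stage("corpus_io", bin_by_year(ctl_in$articles, intervals))
  samples <- with_stage("corpus_io", build_samples(tgt_bin, ctl_bin))

  panel0 <- with_stage("frequency", build_panel(samples$target,
                                                samples$control))
  n_terms_observed <- length(panel0$terms)
  panel <- panel0
  if (!is.null(voc_in$vocab) && !is.null(config$categories)) {
    panel <- with_stage("frequency",
                        filter_categories(panel, voc_in$vocab,
                                          config$categories))
  }
  cat_log <- panel$log$category
  panel <- with_stage("frequency",
                      filter_min_support(panel, config$support_threshold))
  panel <- with_stage("frequency",
                      filter_min_years(panel, config$min_years))

  comparisons <- with_stage("diffstats",
                            compare_all_terms(panel,
                                              continuity = config$continuity,
                                              sentinel = config$sentinel))
  trends <- with_stage("trends",
                       trend_scan(panel,
                                  threshold = config$trend_threshold,
                                  continuity = config$continuity))
  summaries <- list(target = corpus_summary(samples$target),
                    control = corpus_summary(samples$control))
  db_shares <- NULL
  if (!is.null(config$db_totals)) {
    db_shares <- with_stage("frequency", lapply(
      list(target = samples$target$year_sizes,
           control = samples$control$year_sizes),
      normalize_to_database_totals, db_totals = config$db_totals))
  }

  hash_or_null <- function(p) {
    if (is.null(p)) NULL else unname(tools::md5sum(p))
  }
  manifest <- list(
    package = "meshtrends",
    version = as.character(utils::packageVersion("meshtrends")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      categories = config$categories,
      support_threshold = config$support_threshold,
      min_years = config$min_years,
      trend_threshold = config$trend_threshold,
      continuity = config$continuity,
      diff_alpha = config$diff_alpha,
      sentinel = config$sentinel,
      intervals = intervals$label
    ),
    inputs = list(
      target_path = tgt_in$path, target_md5 = hash_or_null(tgt_in$path),
      control_path = ctl_in$path, control_md5 = hash_or_null(ctl_in$path),
      vocabulary_path = voc_in$path,
      vocabulary_md5 = hash_or_null(voc_in$path)
    ),
    articles = list(
      target = list(
        read = unname(n_read["target"]),
        outside_intervals = unname(n_read["target"]) - nrow(tgt_bin),
        shared_removed = samples$target$n_removed_shared,
        analyzed = nrow(samples$target$articles)
      ),
      control = list(
        read = unname(n_read["control"]),
        outside_intervals = unname(n_read["control"]) - nrow(ctl_bin),
        shared_removed = samples$control$n_removed_shared,
        analyzed = nrow(samples$control$articles)
      )
    ),
    terms = list(
      observed = n_terms_observed,
      unmapped_removed = if (is.null(cat_log)) 0L else cat_log$n_unmapped,
      out_of_category_removed = if (is.null(cat_log)) 0L else
        cat_log$n_out_of_category,
      support_removed = panel$log$support$n_removed,
      analyzed = length(panel$terms),
      trend_ineligible = as.list(panel$log$min_years$n_ineligible)
    )
  )

  result <- structure(
    list(panel = panel, comparisons = comparisons, trends = trends,
         summary = summaries, db_shares = db_shares,
         manifest = manifest, config = config),
    class = "meshtrends_run"
  )
  if (!is.null(config$out_dir)) {
    write_run_outputs(result, config$out_dir)
  }
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    wcsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      written <<- c(written, p)
    }
    wcsv(as.data.frame(result$panel), "panel.csv")
    wcsv(result$comparisons, "comparisons.csv")
    wcsv(result$trends, "trends.csv")
    wcsv(result$summary$target$per_year, "summary_target.csv")
    wcsv(result$summary$control$per_year, "summary_control.csv")
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    written <- c(written, mp)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage 'report': ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' @export
print.meshtrends_run <- function(x, ...) {
  cat("<meshtrends_run>\n")
  cat("  terms analyzed: ", length(x$panel$terms), " (of ",
      x$manifest$terms$observed, " observed)\n", sep = "")
  s <- attr(x$trends, "summary")
  if (!is.null(s)) {
    cat("  trends (p <= ", x$config$trend_threshold, "):\n", sep = "")
    print(s)
  }
  invisible(x)
}

#' Wordcloud weight table for one sample
#'
#' Selects the terms significantly enriched on the requested side
#' (BH-adjusted Fisher p-value at most `alpha`, log ratio of matching
#' sign, the zero-control sentinel counting as target-side) and weights
#' each by its pooled relative frequency on that side, so rendered font
#' sizes are proportional to occurrence frequency. Weights are
#' non-increasing in rank order.
#'
#' @param comparisons Result of [compare_all_terms()].
#' @param side `"target"` or `"control"`.
#' @param top_n Keep at most this many terms (default all).
#' @param alpha Significance gate on `fisher_q`.
#' @param vocab Optional vocabulary to annotate each term with its first
#'   category letter (the wordcloud colour key).
#' @return data.frame with columns `term`, `weight`, `category`.
#' @export
wordcloud_table <- function(comparisons, side = c("target", "control"),
                            top_n = Inf, alpha = 0.05, vocab = NULL) {
  side <- match.arg(side)
  if (nrow(comparisons) == 0L) stop("empty comparison table")
  sel <- comparisons$fisher_q <= alpha &
    if (side == "target") comparisons$logratio > 0 else
      comparisons$logratio < 0
  hits <- comparisons[sel, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no significant ", side, "-enriched terms")
    return(data.frame(term = character(), weight = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  }
  weight <- if (side == "target") hits$target_freq else hits$control_freq
  ord <- order(weight, decreasing = TRUE)
  out <- data.frame(term = hits$term[ord],
                    weight = weight[ord],
                    category = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(vocab)) {
    desc <- vocab_lookup(vocab, out$term)
    out$category <- vapply(desc, function(d) {
      if (is.null(d) || length(d$categories) == 0L) NA_character_
      else d$categories[[1L]]
    }, character(1L))
  }
  utils::head(out, top_n)
}

#' Heatmap matrix of per-year term shares
#'
#' Cell (t, y) is the relative frequency of term t in year y for the chosen
#' sample; rows keep the order given in `terms`.
#'
#' @param panel A `freq_panel`.
#' @param sample `"target"` or `"control"`.
#' @param terms Ordered character vector of panel terms.
#' @return Numeric matrix, terms x years.
#' @export
heatmap_matrix <- function(panel, sample = c("target", "control"), terms) {
  sample <- match.arg(sample)
  if (length(terms) == 0L) stop("empty term list")
  missing_terms <- setdiff(terms, panel$terms)
  if (length(missing_terms) > 0L) {
    stop("unknown term(s): ", paste(missing_terms, collapse = ", "))
  }
  relfreq(panel, sample)[terms, , drop = FALSE]
}

#' Descriptive corpus summary
#'
#' Per year: article count, number of unique MeSH terms and mean terms per
#' article; overall: totals plus the unique-term accumulation slope, the
#' mean number of new unique terms each article after the first adds to
#' the collection (articles ordered by year bin, then PMID).
#'
#' @param corpus A `sample_corpus`.
#' @return List with `per_year` (data.frame) and `total` (list with
#'   `n_articles`, `n_unique_terms`, `mean_terms_per_article`,
#'   `accumulation_slope`).
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "sample_corpus"))
  arts <- corpus$articles
  if (nrow(arts) == 0L) stop("empty corpus")
  ord <- order(arts$year_bin, arts$pmid)
  tl <- arts$terms[ord]
  yb <- as.character(arts$year_bin[ord])

  per_year <- do.call(rbind, lapply(names(corpus$year_sizes), function(y) {
    sub <- tl[yb == y]
    data.frame(year = y,
               n_articles = length(sub),
               n_unique_terms = length(unique(unlist(sub,
                                                     use.names = FALSE))),
               mean_terms_per_article =
                 if (length(sub) > 0L) mean(lengths(sub)) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  ul <- unlist(tl, use.names = FALSE)
  art_of <- rep(seq_along(tl), lengths(tl))
  new_per_article <- tabulate(art_of[!duplicated(ul)], nbins = length(tl))
  n <- length(tl)
  slope <- if (n > 1L) sum(new_per_article[-1L]) / (n - 1L) else NA_real_
  list(per_year = per_year,
       total = list(n_articles = n,
                    n_unique_terms = length(unique(ul)),
                    mean_terms_per_article = mean(lengths(tl)),
                    accumulation_slope = slope))
}
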