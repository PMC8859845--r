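# Synthetic annotated-corpus generator with known ground truth.
#
# Emulates two partially overlapping samples of MeSH-annotated articles:
# each article carries a fixed number of terms (10-15 by default, matching
# MEDLINE indexing depth) drawn from a category-structured vocabulary with
# power-law baseline frequencies; selected terms receive a target-vs-control
# enrichment or a linear year-on-year trend. Everything is reproducible
# from the spec's seed, so each pipeline stage can be validated against the
# generative truth without any download.
#
# Term draws use weighted sampling without replacement (Gumbel top-k), so
# per-article term counts are exact and a term's inclusion probability is
# approximately its weight when weights are scaled to sum to the mean
# number of terms per article; the approximation is excellent for terms
# whose weight is a small fraction of the total.

#' Specify a synthetic two-sample corpus
#'
#' Defaults define a scaled-down but proportionate analogue of a decade-long
#' PubMed comparison: 9 yearly bins, 2000 articles per sample per year, a
#' 500-term vocabulary split across categories C/D/E/B, a power-law baseline
#' frequency profile, and 10-15 terms per article.
#'
#' @param seed Integer RNG seed; the whole corpus is a deterministic
#'   function of the spec including this seed.
#' @param years Integer vector of calendar years (one bin per year).
#' @param n_target,n_control Articles per year in each sample (scalar or
#'   per-year vector).
#' @param vocabulary_size Number of generated descriptors.
#' @param category_props Named proportions of the vocabulary per category
#'   letter; must sum to 1.
#' @param terms_per_article Integer range `c(min, max)`; each article draws
#'   a uniform count in this range.
#' @param baseline_shape Power-law exponent s of the baseline profile
#'   (term i gets weight proportional to i^-s).
#' @param differential `NULL` or a data.frame with columns `term` (index or
#'   generated name) and `log2_enrichment`: the term's target-sample weight
#'   is its baseline times 2^enrichment.
#' @param trend `NULL` or a data.frame with columns `term`, `sample`
#'   (`"target"`/`"control"`), `start_freq`, `end_freq`: that sample's
#'   weight for the term interpolates linearly across the bins.
#' @param overlap_fraction Share of each year's smaller sample emitted with
#'   PMIDs present in both samples (exercises the shared-PMID exclusion).
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1L,
                            years = 2009:2017,
                            n_target = 2000L,
                            n_control = 2000L,
                            vocabulary_size = 500L,
                            category_props = c(C = 0.4, D = 0.3,
                                               E = 0.2, B = 0.1),
                            terms_per_article = c(10L, 15L),
                            baseline_shape = 0.5,
                            differential = NULL,
                            trend = NULL,
                            overlap_fraction = 0) {
  years <- as.integer(years)
  ny <- length(years)
  stopifnot(ny >= 1L, vocabulary_size >= 1L)
  n_target <- rep_len(as.integer(n_target), ny)
  n_control <- rep_len(as.integer(n_control), ny)
  if (any(n_target <= 0L) || any(n_control <= 0L)) {
    stop("per-year sample sizes must be positive")
  }
  terms_per_article <- as.integer(range(terms_per_article))
  if (terms_per_article[1L] < 1L ||
      terms_per_article[2L] > vocabulary_size) {
    stop("infeasible spec: terms_per_article must lie in [1, vocabulary_size]")
  }
  if (abs(sum(category_props) - 1) > 1e-8 || any(category_props < 0) ||
      is.null(names(category_props)) ||
      !all(grepl("^[A-Z]$", names(category_props)))) {
    stop("category_props must be named by single letters and sum to 1")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  if (!is.null(differential)) {
    stopifnot(is.data.frame(differential),
              all(c("term", "log2_enrichment") %in% names(differential)))
  }
  if (!is.null(trend)) {
    stopifnot(is.data.frame(trend),
              all(c("term", "sample", "start_freq", "end_freq")
                  %in% names(trend)),
              all(trend$sample %in% c("target", "control")),
              all(trend$start_freq >= 0 & trend$start_freq <= 1),
              all(trend$end_freq >= 0 & trend$end_freq <= 1))
  }
  structure(
    list(seed = as.integer(seed), years = years,
         n_target = n_target, n_control = n_control,
         vocabulary_size = as.integer(vocabulary_size),
         category_props = category_props,
         terms_per_article = terms_per_article,
         baseline_shape = baseline_shape,
         differential = differential, trend = trend,
         overlap_fraction = overlap_fraction),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> seed ", x$seed, ": ", length(x$years),
      " years, ", sum(x$n_target), "/", sum(x$n_control),
      " target/control articles, ", x$vocabulary_size, " terms\n", sep = "")
  invisible(x)
}

# Resolve user term references (index or generated name) to indices.
resolve_terms <- function(ref, term_names) {
  if (is.numeric(ref)) {
    idx <- as.integer(ref)
    if (any(idx < 1L | idx > length(term_names))) {
      stop("term index out of range")
    }
    return(idx)
  }
  idx <- match(ref, term_names)
  if (anyNA(idx)) {
    stop("unknown term(s): ", paste(ref[is.na(idx)], collapse = ", "))
  }
  idx
}

# Draw term sets for n articles with per-term weights w (Gumbel top-k).
draw_block <- function(w, n, k_range, term_names) {
  V <- length(w)
  ks <- seq.int(k_range[1L], k_range[2L])
  k <- ks[sample.int(length(ks), n, replace = TRUE)]
  if (sum(w > 0) < max(k)) {
    stop("infeasible spec: fewer positive-weight terms than terms per article")
  }
  lw <- ifelse(w > 0, log(w), -Inf)
  G <- matrix(lw, n, V, byrow = TRUE) -
    log(-log(matrix(stats::runif(n * V), n, V)))
  lapply(seq_len(n), function(r) {
    term_names[order(G[r, ], decreasing = TRUE)[seq_len(k[r])]]
  })
}

#' Generate a synthetic two-sample corpus
#'
#' Materializes a [simulation_spec()]: a generated vocabulary, target and
#' control article tables (PMID, date, term set) and a ground-truth table
#' labelling every term as null, differential, trend, or both, together
#' with its generative parameters. PMIDs are sequential integers
#' partitioned into target-only, control-only and shared blocks; shared
#' articles are emitted into both samples verbatim.
#'
#' @param spec A `simulation_spec`.
#' @return List with elements `target`, `control` (article data.frames as
#'   from [read_articles()]), `vocabulary` (a `mesh_vocabulary`), `truth`
#'   (data.frame) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  V <- spec$vocabulary_size
  ny <- length(spec$years)
  term_names <- sprintf("term%04d", seq_len(V))

  # vocabulary: category letters in stated proportions, synthetic tree codes
  n_per_cat <- floor(spec$category_props * V)
  rem <- V - sum(n_per_cat)
  if (rem > 0L) {
    frac <- spec$category_props * V - n_per_cat
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_per_cat[bump] <- n_per_cat[bump] + 1L
  }
  cat_letters <- sample(rep(names(spec$category_props), times = n_per_cat))
  trees <- sprintf("%s%02d.%03d", cat_letters,
                   sample.int(99L, V, replace = TRUE),
                   sample.int(999L, V, replace = TRUE))
  vocab <- new_vocabulary(lapply(seq_len(V), function(i) {
    mesh_descriptor(sprintf("X%06d", i), term_names[i], trees[i])
  }))

  # weights: baseline scaled so the totals match the mean terms per article,
  # making a term's weight its approximate per-article inclusion probability
  kbar <- mean(spec$terms_per_article)
  b <- seq_len(V)^(-spec$baseline_shape)
  b <- b / sum(b) * kbar
  if (max(b) >= 1) {
    stop("infeasible spec: baseline profile too concentrated ",
         "(leading term weight >= 1)")
  }
  W <- list(target = matrix(b, V, ny), control = matrix(b, V, ny))

  truth <- data.frame(term = term_names, category = cat_letters,
                      class = "null", baseline_freq = b,
                      log2_enrichment = NA_real_,
                      trend_sample = NA_character_,
                      trend_start = NA_real_, trend_end = NA_real_,
                      stringsAsFactors = FALSE)
  if (!is.null(spec$differential)) {
    idx <- resolve_terms(spec$differential$term, term_names)
    enr <- spec$differential$log2_enrichment
    W$target[idx, ] <- b[idx] * 2^enr
    if (any(W$target[idx, 1L] >= 1)) {
      stop("infeasible spec: differential enrichment pushes a weight >= 1")
    }
    truth$class[idx] <- "differential"
    truth$log2_enrichment[idx] <- enr
  }
  if (!is.null(spec$trend)) {
    idx <- resolve_terms(spec$trend$term, term_names)
    for (r in seq_along(idx)) {
      i <- idx[r]
      W[[spec$trend$sample[r]]][i, ] <-
        seq(spec$trend$start_freq[r], spec$trend$end_freq[r],
            length.out = ny)
      truth$class[i] <- if (truth$class[i] == "differential") {
        "differential+trend"
      } else {
        "trend"
      }
      truth$trend_sample[i] <- spec$trend$sample[r]
      truth$trend_start[i] <- spec$trend$start_freq[r]
      truth$trend_end[i] <- spec$trend$end_freq[r]
    }
  }

  next_id <- 1L
  take_ids <- function(n) {
    ids <- seq.int(next_id, length.out = n)
    next_id <<- next_id + n
    ids
  }
  tgt <- list()
  ctl <- list()
  for (y in seq_len(ny)) {
    nt <- spec$n_target[y]
    nc <- spec$n_control[y]
    nsh <- as.integer(round(spec$overlap_fraction * min(nt, nc)))
    date <- as.Date(sprintf("%d-07-01", spec$years[y]))
    mk <- function(n, w) {
      if (n == 0L) return(NULL)
      articles_frame(take_ids(n), rep(date, n),
                     draw_block(w, n, spec$terms_per_article, term_names))
    }
    t_only <- mk(nt - nsh, W$target[, y])
    c_only <- mk(nc - nsh, W$control[, y])
    shared <- mk(nsh, W$control[, y])  # background articles caught by both
    tgt[[y]] <- rbind(t_only, shared)
    ctl[[y]] <- rbind(c_only, shared)
  }
  list(target = do.call(rbind, tgt), control = do.call(rbind, ctl),
       vocabulary = vocab, truth = truth, spec = spec)
}

#' Write an article table in the TSV interchange format
#'
#' `pmid <TAB> date <TAB> semicolon-joined MeSH names`, the format
#' [read_articles()] consumes.
#'
#' @param articles Article data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(articles, path) {
  lines <- paste(articles$pmid, format(articles$date, "%Y-%m-%d"),
                 vapply(articles$terms, paste, character(1L),
                        collapse = ";"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a vocabulary in the 3-column TSV format
#'
#' @param vocab A `mesh_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  lines <- vapply(vocab$descriptors, function(d) {
    paste(d$ui, d$name, paste(d$tree_numbers, collapse = ";"), sep = "\t")
  }, character(1L))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Score pipeline calls against generative ground truth
#'
#' Confusion summaries for the two detector outputs: differential calls
#' (`fisher_q <= alpha` with the sign of the log ratio matching the
#' injected enrichment) scored against terms of class `differential`, and
#' trend calls (classified direction matching the injected slope sign in
#' the injected sample) scored against terms of class `trend`. False
#' positives are counted among terms of class `null` only; injected terms
#' missing from the results (e.g. removed by a filter) count as misses.
#'
#' @param truth Ground-truth table from [generate_corpus()].
#' @param comparisons Optional result of [compare_all_terms()].
#' @param trends Optional result of [trend_scan()].
#' @param alpha Significance gate on `fisher_q` for differential calls.
#' @return List with components `differential` and/or `trend`, each a list
#'   of counts (`tp`, `fn`, `fp`, `n_true`, `n_null`) and rates (`recall`,
#'   `fpr`).
#' @export
truth_score <- function(truth, comparisons = NULL, trends = NULL,
                        alpha = 0.05) {
  out <- list()
  if (!is.null(comparisons)) {
    unknown <- setdiff(comparisons$term, truth$term)
    if (length(unknown) > 0L) {
      stop("result terms absent from ground truth: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    m <- merge(comparisons, truth, by = "term")
    called <- m$fisher_q <= alpha
    is_diff <- grepl("differential", m$class)
    sign_ok <- sign(m$logratio) == sign(m$log2_enrichment)
    tp <- sum(is_diff & called & sign_ok, na.rm = TRUE)
    n_true <- sum(grepl("differential", truth$class))
    is_null <- m$class == "null"
    fp <- sum(is_null & called)
    n_null <- sum(is_null)
    out$differential <- list(
      tp = tp, fn = n_true - tp, fp = fp,
      n_true = n_true, n_null = n_null,
      recall = if (n_true > 0L) tp / n_true else NA_real_,
      fpr = if (n_null > 0L) fp / n_null else NA_real_
    )
  }
  if (!is.null(trends)) {
    unknown <- setdiff(trends$term, truth$term)
    if (length(unknown) > 0L) {
      stop("result terms absent from ground truth: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    tr_truth <- truth[grepl("trend", truth$class), , drop = FALSE]
    expected <- ifelse(tr_truth$trend_end > tr_truth$trend_start,
                       "up", "down")
    key <- paste(trends$term, trends$sample)
    hit <- match(paste(tr_truth$term, tr_truth$trend_sample), key)
    tp <- sum(!is.na(hit) & trends$direction[hit] == expected)
    n_true <- nrow(tr_truth)
    null_terms <- truth$term[truth$class == "null"]
    null_rows <- trends$term %in% null_terms
    fp <- sum(null_rows & trends$direction != "none")
    n_null <- sum(null_rows)
    out$trend <- list(
      tp = tp, fn = n_true - tp, fp = fp,
      n_true = n_true, n_null = n_null,
      recall = if (n_true > 0L) tp / n_true else NA_real_,
      fpr = if (n_null > 0L) fp / n_null else NA_real_
    )
  }
  if (length(out) == 0L) {
    stop("provide at least one of 'comparisons' or 'trends'")
  }
  out
}
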