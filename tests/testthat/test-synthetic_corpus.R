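small_spec <- function(...) {
  simulation_spec(seed = 77, years = 2014:2016, n_target = 120,
                  n_control = 120, vocabulary_size = 150,
                  terms_per_article = c(10, 15), ...)
}

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_corpus(small_spec())
  b <- generate_corpus(small_spec())
  fa <- tempfile(); fb <- tempfile()
  write_corpus_tsv(a$target, fa)
  write_corpus_tsv(b$target, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth, b$truth)
  # changing only the seed changes the draws but not the design
  c <- generate_corpus(simulation_spec(seed = 78, years = 2014:2016,
                                       n_target = 120, n_control = 120,
                                       vocabulary_size = 150))
  expect_false(identical(readLines(fa), {
    fc <- tempfile(); write_corpus_tsv(c$target, fc); readLines(fc)
  }))
  expect_equal(mean(lengths(a$target$terms)),
               mean(lengths(c$target$terms)), tolerance = 0.05)
})

test_that("every article carries a term count inside the configured range", {
  corp <- generate_corpus(small_spec())
  for (side in c("target", "control")) {
    ln <- lengths(corp[[side]]$terms)
    expect_true(all(ln >= 10L & ln <= 15L))
    expect_true(all(vapply(corp[[side]]$terms, anyDuplicated, integer(1))
                    == 0L))
  }
  # ground truth covers every generated term exactly once
  expect_identical(sort(corp$truth$term),
                   sort(unname(vapply(corp$vocabulary$descriptors,
                                      `[[`, character(1), "name"))))
  expect_false(anyDuplicated(corp$truth$term) > 0L)
})

test_that("an injected -2 enrichment is recovered by the pooled log ratio", {
  spec <- simulation_spec(
    seed = 88, years = 2016, n_target = 5000, n_control = 5000,
    vocabulary_size = 200, terms_per_article = c(10, 15),
    differential = data.frame(term = 20L, log2_enrichment = -2))
  corp <- generate_corpus(spec)
  panel <- panel_from_articles(corp$target, corp$control, 2016)
  cmp <- compare_all_terms(filter_min_support(panel))
  row <- cmp[cmp$term == "term0020", ]
  x1 <- panel$counts$target["term0020", ]
  x2 <- panel$counts$control["term0020", ]
  se <- sqrt(1 / x1 - 1 / 5000 + 1 / x2 - 1 / 5000) / log(2)
  expect_lt(abs(row$logratio - (-2)), 3 * se)
  expect_identical(row$direction, "control")
})

test_that("empirical term frequencies track the specified probabilities", {
  spec <- simulation_spec(seed = 91, years = 2016, n_target = 4000,
                          n_control = 50, vocabulary_size = 200)
  corp <- generate_corpus(spec)
  panel <- panel_from_articles(corp$target, corp$control, 2016)
  rf <- relfreq(panel, "target")
  for (i in c(5L, 40L, 150L)) {
    q <- corp$truth$baseline_freq[i]
    obs <- rf[sprintf("term%04d", i), 1L]
    se <- sqrt(q * (1 - q) / 4000)
    # 3 SE plus a small allowance for the weighted-draw approximation
    expect_lt(abs(obs - q), 3 * se + 0.1 * q)
  }
})

test_that("the PMID overlap block is emitted into both samples", {
  corp <- generate_corpus(small_spec(overlap_fraction = 0.2))
  shared <- intersect(corp$target$pmid, corp$control$pmid)
  expect_identical(length(shared), 3L * as.integer(round(0.2 * 120)))
  s <- build_samples(bin_by_year(corp$target, year_intervals(2014:2016)),
                     bin_by_year(corp$control, year_intervals(2014:2016)))
  expect_identical(sort(s$shared_pmids), sort(shared))
  expect_identical(nrow(s$target$articles), 3L * (120L - 24L))
})

test_that("infeasible specifications fail before generation", {
  expect_error(simulation_spec(vocabulary_size = 8,
                               terms_per_article = c(10, 15)),
               "infeasible")
  expect_error(simulation_spec(overlap_fraction = 1), "overlap_fraction")
  expect_error(simulation_spec(category_props = c(C = 0.5, D = 0.2)),
               "sum to 1")
})

test_that("truth scoring reports calibration-style confusion summaries", {
  truth <- data.frame(term = c("a", "b", "c"),
                      category = "C",
                      class = c("differential", "null", "null"),
                      baseline_freq = 0.1,
                      log2_enrichment = c(2, NA, NA),
                      trend_sample = NA_character_,
                      trend_start = NA_real_, trend_end = NA_real_,
                      stringsAsFactors = FALSE)
  perfect <- data.frame(term = c("a", "b", "c"),
                        fisher_q = c(0.001, 0.9, 0.7),
                        logratio = c(2.1, 0.01, -0.02),
                        stringsAsFactors = FALSE)
  sc <- truth_score(truth, comparisons = perfect)
  expect_equal(sc$differential$recall, 1)
  expect_equal(sc$differential$fpr, 0)
  stranger <- perfect
  stranger$term[1] <- "unknown"
  expect_error(truth_score(truth, comparisons = stranger),
               "absent from ground truth")
  expect_error(truth_score(truth), "at least one")
})
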