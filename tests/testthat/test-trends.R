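test_that("Mann-Kendall statistics match hand-computed values", {
  mk <- mann_kendall(1:9)
  expect_identical(mk$S, 36)
  expect_equal(mk$varS, 92)
  expect_equal(mk$z, 35 / sqrt(92), tolerance = 1e-12)
  expect_equal(mk$p.value, 2.633e-4, tolerance = 1e-3)
  mk2 <- mann_kendall(c(1, 3, 2, 4))
  expect_identical(mk2$S, 4)
  expect_equal(mk2$varS, 26 / 3)
  expect_equal(mk2$p.value, 0.3082, tolerance = 1e-4)
  expect_error(mann_kendall(c(1, 2)), "at least 3")
  tied <- mann_kendall(rep(2, 6))
  expect_true(tied$degenerate)
  expect_identical(tied$S, 0)
  expect_equal(tied$p.value, 1)
})

test_that("Mann-Kendall is antisymmetric and rank-invariant", {
  set.seed(11)
  for (i in 1:25) {
    x <- stats::rnorm(sample(4:12, 1))
    f <- mann_kendall(x)
    r <- mann_kendall(rev(x))
    expect_identical(r$S, -f$S)
    expect_equal(r$p.value, f$p.value)
    g <- mann_kendall(exp(x))   # strictly monotone transform
    expect_identical(g$S, f$S)
    expect_equal(g$p.value, f$p.value)
  }
})

test_that("exact permutation p matches enumeration and cor.test's exact tail", {
  expect_equal(mann_kendall_exact(c(1, 3, 2, 4))$p.value, 1 / 3)
  set.seed(23)
  for (n in 4:7) {
    for (rep in 1:4) {
      x <- sample(stats::rnorm(n))   # distinct values
      mk <- mann_kendall_exact(x)
      expect_identical(mk$S, s_oracle(x))
      # independent enumeration of all n! orderings
      P <- perms_oracle(n)
      S_all <- apply(P, 1L, function(o) s_oracle(x[o]))
      expect_equal(mk$p.value, mean(abs(S_all) >= abs(mk$S)))
      # cor.test's exact Kendall tail is an independent oracle
      ref <- stats::cor.test(x, seq_len(n), method = "kendall",
                             exact = TRUE)
      expect_equal(mk$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("normal and exact decisions agree outside a narrow boundary band", {
  set.seed(29)
  ok <- vapply(1:60, function(i) {
    n <- sample(4:7, 1)
    x <- sample(stats::rnorm(n))
    pn <- mann_kendall(x)$p.value
    pe <- mann_kendall_exact(x)$p.value
    agree <- (pn <= 0.01) == (pe <= 0.01)
    agree || (pe > 0.002 && pe < 0.05)
  }, logical(1))
  expect_true(all(ok))
})

test_that("trend classification applies the 0.01 threshold with sign of S", {
  expect_identical(classify_trend(0.005, 20), "up")
  expect_identical(classify_trend(0.02, 20), "none")
  expect_identical(classify_trend(0.005, -20), "down")
  expect_identical(classify_trend(0.005, 0), "none")
  expect_identical(classify_trend(c(0.005, 0.5), c(-3, -3)),
                   c("down", "none"))
  expect_error(classify_trend(0.5, 1, threshold = 0), "threshold")
})

test_that("frequency deltas and Sen's slope summarize change", {
  expect_equal(frequency_delta(c(0.79, 0.45)), -34)
  expect_equal(frequency_delta(rep(0.2, 5)), 0)
  expect_equal(frequency_delta(c(0.10, 0.20, 0.30)), 20)
  expect_equal(sen_slope(c(0.10, 0.20, 0.30)), 0.10)
  # median of pairwise slopes by direct enumeration
  x <- c(0.1, 0.5, 0.2, 0.4)
  slopes <- c((x[2] - x[1]) / 1, (x[3] - x[1]) / 2, (x[4] - x[1]) / 3,
              (x[3] - x[2]) / 1, (x[4] - x[2]) / 2, (x[4] - x[3]) / 1)
  expect_equal(sen_slope(x), stats::median(slopes))
  expect_error(frequency_delta(0.3), "at least 2")
})

test_that("trend_scan recovers an injected monotone increase", {
  spec <- simulation_spec(
    seed = 51, years = 2009:2017, n_target = 800, n_control = 800,
    vocabulary_size = 150, terms_per_article = c(10, 15),
    trend = data.frame(term = c(30L, 31L),
                       sample = c("target", "target"),
                       start_freq = c(0.01, 0.12),
                       end_freq = c(0.12, 0.01)))
  corp <- generate_corpus(spec)
  panel <- panel_from_articles(corp$target, corp$control, 2009:2017)
  panel <- filter_min_years(filter_min_support(panel))
  tr <- trend_scan(panel)
  expect_identical(tr$direction[tr$term == "term0030" &
                                  tr$sample == "target"], "up")
  expect_identical(tr$direction[tr$term == "term0031" &
                                  tr$sample == "target"], "down")
  expect_gt(tr$delta_pp[tr$term == "term0030" & tr$sample == "target"], 5)
  sc <- truth_score(corp$truth, trends = tr)
  expect_equal(sc$trend$recall, 1)
})

test_that("trend_scan is invariant under order-preserving year relabelling", {
  fx <- bookkeeping_fixture()
  panel <- panel_from_articles(fx$target, fx$control, fx$years)
  panel <- filter_min_years(filter_min_support(panel))
  relabel <- function(p, labels) {
    p$years <- labels
    names(p$years_ok) <- labels
    for (s in c("target", "control")) {
      colnames(p$counts[[s]]) <- labels
      names(p$sizes[[s]]) <- labels
    }
    p
  }
  panel2 <- relabel(panel, paste0("bin", seq_along(panel$years)))
  a <- trend_scan(panel)
  b <- trend_scan(panel2)
  expect_identical(a[c("term", "sample", "S", "p", "direction")],
                   b[c("term", "sample", "S", "p", "direction")])
})
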