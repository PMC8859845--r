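test_that("two-proportion chi-square reproduces the small/large power flip", {
  small <- two_proportion_test(9, 10, 7, 10)
  expect_equal(small$statistic, 0.3125)
  expect_equal(small$p.value, 0.5762, tolerance = 1e-4)
  expect_gt(small$p.value, 0.05)
  large <- two_proportion_test(90, 100, 70, 100)
  expect_equal(large$statistic, 11.28125)
  expect_lt(large$p.value, 0.05)
  same <- two_proportion_test(5, 10, 5, 10, continuity = FALSE)
  expect_equal(same$p.value, 1)
  degen <- two_proportion_test(0, 10, 0, 10)
  expect_true(degen$degenerate)
  expect_equal(degen$p.value, 1)
})

test_that("chi-square matches prop.test/chisq.test on an exhaustive grid", {
  for (n1 in c(3L, 7L, 12L)) {
    for (n2 in c(4L, 12L)) {
      for (x1 in 0:n1) {
        for (x2 in 0:n2) {
          pooled <- (x1 + x2) / (n1 + n2)
          if (pooled == 0 || pooled == 1) next
          tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
          for (corr in c(TRUE, FALSE)) {
            mine <- two_proportion_test(x1, n1, x2, n2, continuity = corr)
            ref <- suppressWarnings(stats::chisq.test(tab, correct = corr))
            expect_equal(mine$statistic, unname(ref$statistic),
                         tolerance = 1e-12)
            expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
          }
        }
      }
    }
  }
  # spot-check against prop.test, the reference interface
  ref <- suppressWarnings(stats::prop.test(c(9, 7), c(10, 10)))
  expect_equal(two_proportion_test(9, 10, 7, 10)$p.value, ref$p.value)
})

test_that("uncorrected chi-square equals the squared z-test; test is symmetric", {
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    pooled <- (x1 + x2) / (n1 + n2)
    if (pooled == 0 || pooled == 1) next
    z2 <- ((x1 / n1 - x2 / n2)^2) /
      (pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    expect_equal(two_proportion_test(x1, n1, x2, n2,
                                     continuity = FALSE)$statistic,
                 z2, tolerance = 1e-10)
    a <- two_proportion_test(x1, n1, x2, n2)
    b <- two_proportion_test(x2, n2, x1, n1)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p.value, b$p.value)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(0.04), 0.04)
  set.seed(17)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("Fisher aggregation follows the 2k-df chi-square form", {
  one <- fisher_aggregate(0.05)
  expect_equal(one$p.value, 0.05, tolerance = 1e-12)  # df=2: p = exp(-x/2)
  none <- fisher_aggregate(c(1, 1))
  expect_equal(none$statistic, 0)
  expect_equal(none$p.value, 1)
  two <- fisher_aggregate(c(0.1, 0.1))
  expect_equal(two$statistic, 9.21034, tolerance = 1e-5)
  expect_identical(two$df, 4L)
  expect_equal(two$p.value, 0.0560517, tolerance = 1e-6)
  # closed form at df=4: (1 + x/2) exp(-x/2)
  x <- two$statistic
  expect_equal(two$p.value, (1 + x / 2) * exp(-x / 2), tolerance = 1e-12)
  # evidence accumulates: more copies of a small p, smaller aggregate
  agg <- vapply(1:6, function(k) fisher_aggregate(rep(0.1, k))$p.value,
                numeric(1))
  expect_true(all(diff(agg) < 0))
  expect_warning(z <- fisher_aggregate(c(0, 0.5)), "clamped")
  expect_true(is.finite(z$statistic))
  expect_error(fisher_aggregate(numeric(0)), "empty")
})

test_that("log ratio encodes fold change with the zero-control sentinel", {
  expect_equal(log_ratio(0.005, 0.020), -2)   # four-fold control enrichment
  expect_equal(log_ratio(0.3, 0.3), 0)
  expect_equal(log_ratio(0.004, 0), 10)
  expect_equal(log_ratio(0.004, 0, sentinel = 12), 12)
  set.seed(5)
  a <- stats::runif(25, 0.001, 0.5)
  b <- stats::runif(25, 0.001, 0.5)
  expect_equal(log_ratio(a, b), -log_ratio(b, a))
  expect_error(log_ratio(0, 0), "both")
  expect_error(log_ratio(-0.1, 0.2), "non-negative")
})

test_that("compare_all_terms aggregates per-year tests per the panel contract", {
  years <- 2011:2014
  # null term identical everywhere; diff term 4x control-enriched
  mk <- function(null_k, diff_k, pmid0) {
    blocks <- lapply(seq_along(years), function(yi) {
      slots <- rep(list(character(0)), 20L)
      for (s in seq_len(null_k)) slots[[s]] <- c(slots[[s]], "nullT")
      for (s in seq_len(diff_k)) slots[[s]] <- c(slots[[s]], "diffT")
      fixture_articles(pmid0 + (yi - 1L) * 20L + 0:19,
                       rep(years[yi], 20L), slots)
    })
    do.call(rbind, blocks)
  }
  panel <- panel_from_articles(mk(8L, 2L, 100L), mk(8L, 8L, 900L), years)
  cmp <- compare_all_terms(panel)
  nullrow <- cmp[cmp$term == "nullT", ]
  expect_equal(nullrow$logratio, 0)
  expect_gt(nullrow$fisher_p, 0.9)
  diffrow <- cmp[cmp$term == "diffT", ]
  expect_equal(diffrow$logratio, -2)          # 2/20 vs 8/20 pooled
  expect_identical(diffrow$direction, "control")
  expect_identical(unique(cmp$fisher_df), 2L * length(years))
  P <- attr(cmp, "per_year_p")
  Q <- attr(cmp, "per_year_q")
  expect_true(all(Q >= P))
  expect_identical(dim(P), c(2L, 4L))
  LR <- attr(cmp, "per_year_logratio")
  expect_equal(unname(LR["diffT", ]), rep(-2, 4))
})
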