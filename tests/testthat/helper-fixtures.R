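# Shared fixtures and independent oracles, all built in code.

# Article data.frame in the shape read_articles() produces.
fixture_articles <- function(pmid, year, terms) {
  df <- data.frame(pmid = as.integer(pmid),
                   date = as.Date(paste0(year, "-06-15")))
  df$terms <- lapply(terms, function(t) unique(trimws(as.character(t))))
  df
}

# Brute-force Mann-Kendall S: explicit double loop over ordered pairs.
s_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) s <- s + sign(x[j] - x[i])
  }
  s
}

# All permutations of 1..n, built by interleaving (independent of the
# package's own enumeration).
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
          sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
  }))
}

# Hand Benjamini-Hochberg step-up: sort, scale by m/rank, cumulative min
# from the largest rank, cap at 1, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Deterministic bookkeeping corpus with planted shared PMIDs, low-support
# terms, out-of-category terms, an unmapped term and short (<6-year) series.
bookkeeping_fixture <- function() {
  years <- 2009:2017
  on5 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  schedule <- list(
    keepA     = list(target = rep(2, 9), control = rep(2, 9)),
    keepB     = list(target = rep(1, 9), control = rep(1, 9)),
    lowC      = list(target = on5,       control = rep(1, 9)),
    lowD      = list(target = rep(1, 9), control = on5),
    lowE      = list(target = on5,       control = on5),
    catB1     = list(target = rep(2, 9), control = rep(2, 9)),
    catB2     = list(target = rep(2, 9), control = rep(2, 9)),
    unmappedX = list(target = rep(1, 9), control = rep(1, 9)),
    fewA      = list(target = 2 * on5,   control = 2 * on5),
    fewB      = list(target = 2 * on5,
                     control = c(2, 2, 2, 2, 2, 2, 2, 0, 0))
  )
  n_slots <- 6L
  build <- function(sample, pmid0) {
    blocks <- lapply(seq_along(years), function(yi) {
      slots <- rep(list(character(0)), n_slots)
      for (tm in names(schedule)) {
        k <- schedule[[tm]][[sample]][yi]
        if (k > 0) for (s in seq_len(k)) slots[[s]] <- c(slots[[s]], tm)
      }
      fixture_articles(pmid0 + (yi - 1L) * n_slots + seq_len(n_slots) - 1L,
                       rep(years[yi], n_slots), slots)
    })
    do.call(rbind, blocks)
  }
  target <- build("target", 1000L)
  control <- build("control", 2000L)
  shared <- fixture_articles(9001:9005, rep(2009L, 5L),
                             rep(list("keepA"), 5L))
  vocab_tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "V001\tkeepA\tC01.100",
    "V002\tkeepB\tD02.200",
    "V003\tlowC\tC03.300",
    "V004\tlowD\tD04.400",
    "V005\tlowE\tE05.500",
    "V006\tcatB1\tB01.100",
    "V007\tcatB2\tB02.200",
    "V008\tfewA\tE06.300",
    "V009\tfewB\tC07.400"
  ), vocab_tsv)
  list(
    target = rbind(target, shared),
    control = rbind(control, shared),
    vocab = load_vocabulary(vocab_tsv),
    years = years,
    planted = list(shared = 5L, unmapped = 1L, out_of_category = 2L,
                   low_support = 3L,
                   trend_ineligible = c(target = 2L, control = 1L),
                   analyzed = 4L, observed = 10L)
  )
}

# Build a freq_panel straight from two article tables on calendar years.
panel_from_articles <- function(target, control, years, ...) {
  iv <- year_intervals(years)
  s <- build_samples(bin_by_year(target, iv), bin_by_year(control, iv))
  build_panel(s$target, s$control)
}
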