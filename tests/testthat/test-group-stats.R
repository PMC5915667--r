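expand_reference_labels <- function() {
  counts <- reference_cohort_counts()
  pat <- character(0)
  seg <- character(0)
  for (p in rownames(counts)) {
    for (s in colnames(counts)) {
      k <- counts[p, s]
      if (k > 0) {
        pat <- c(pat, rep(p, k))
        seg <- c(seg, rep(s, k))
      }
    }
  }
  ids <- sprintf("r%03d", seq_along(pat))
  list(patterns = stats::setNames(pat, ids), segments = stats::setNames(seg, ids))
}

test_that("contingency tables cross-tabulate exactly", {
  pat <- c(a = "shared", b = "shared")
  seg <- c(a = "compensated", b = "compensated")
  tab <- build_contingency(pat, seg)
  expect_equal(tab$counts["shared", "compensated"], 2)
  expect_equal(tab$total, 2)
  expect_equal(contingency_percentages(tab)$rows["shared", "compensated"], 100)

  expect_error(build_contingency(pat, seg[1]), "only in patterns: b")
  empty <- build_contingency(stats::setNames(character(0), character(0)),
                             stats::setNames(character(0), character(0)))
  expect_equal(empty$total, 0)
})

test_that("the reference cohort counts reproduce the published margins", {
  ref <- expand_reference_labels()
  tab <- build_contingency(ref$patterns, ref$segments)
  expect_equal(tab$total, 231)
  expect_equal(unname(tab$col_totals), c(114, 37, 43, 37))
  perc <- contingency_percentages(tab)
  expect_equal(unname(perc$total), c(49.4, 16.0, 18.6, 16.0))
  expect_equal(perc$rows["self-contained", "compensated"], 73)
  expect_equal(perc$rows["tacit leader", "compensated"], 38)
  expect_equal(unname(tab$row_totals[c("tacit leader", "shared")]), c(61, 24))
})

test_that("subgroup comparison switches between z and Fisher", {
  z <- compare_to_population(30, 41, 114, 231)
  expect_match(z$method, "continuity")
  expect_lt(z$p_value, 0.01)
  expect_equal(z$sub_prop, 30 / 41)

  # small expected cell: Fisher branch, cross-checked by tail enumeration
  f <- compare_to_population(1, 35, 37, 231)
  expect_equal(f$method, "Fisher exact")
  expect_equal(f$p_value, oracle_fisher_p(1, 34, 37, 194), tolerance = 1e-10)

  eq <- compare_to_population(10, 20, 50, 100)
  expect_gte(eq$p_value, 0.99)

  expect_error(compare_to_population(5, 0, 1, 10), "sub_n")
  expect_error(compare_to_population(11, 10, 1, 10), "counts")
})

test_that("two-sided p-values are symmetric in the two samples", {
  cases <- list(c(3, 10, 20, 60), c(1, 35, 37, 231), c(30, 41, 114, 231))
  for (x in cases) {
    a <- compare_to_population(x[1], x[2], x[3], x[4])
    b <- compare_to_population(x[3], x[4], x[1], x[2])
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    a2 <- compare_to_population(x[1], x[2], x[3], x[4], variant = "z_uncorrected",
                                fisher_threshold = 0)
    b2 <- compare_to_population(x[3], x[4], x[1], x[2], variant = "z_uncorrected",
                                fisher_threshold = 0)
    expect_equal(a2$p_value, b2$p_value, tolerance = 1e-12)
  }
})

test_that("Fisher p-values equal exhaustive hypergeometric tail sums", {
  for (n in 1:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b == 0) next  # no subgroup to compare
      got <- compare_to_population(a, a + b, cc, cc + d,
                                   fisher_threshold = Inf)
      expect_equal(got$p_value, oracle_fisher_p(a, b, cc, d),
                   tolerance = 1e-10)
    }
  }
})

test_that("p-values increase as the subgroup approaches the cohort rate", {
  # uncorrected z on a fixed design: 20-patient subgroup vs 50/100 cohort
  p <- vapply(0:10, function(a) {
    compare_to_population(a, 20, 50, 100, variant = "z_uncorrected",
                          fisher_threshold = 0)$p_value
  }, numeric(1))
  expect_true(!is.unsorted(p))
})

test_that("the comparison sweep flags the reference cohort's findings", {
  ref <- expand_reference_labels()
  tab <- build_contingency(ref$patterns, ref$segments)
  res <- run_all_comparisons(tab, variant = "z_uncorrected",
                             fisher_threshold = 0)
  expect_equal(nrow(res), 28)  # 7 patterns x 4 segments
  pick <- function(p, s) res[res$pattern == p & res$segment == s, ]
  sc <- pick("self-contained", "compensated")
  expect_lt(sc$p_value, 0.01)
  expect_true(sc$significant)
  expect_equal(sc$sub_pct, 100 * 30 / 41)
  ph <- pick("participatory", "highly decompensated")
  expect_true(ph$significant)
  srl <- pick("self-referred leader", "highly decompensated")
  expect_lt(abs(srl$p_value - 0.05), 0.01)
  # outlier row is never compared
  expect_false("outlier" %in% res$pattern)

  # a pattern matching the cohort margin exactly is never flagged
  pat <- c(stats::setNames(rep("shared", 10), sprintf("s%02d", 1:10)),
           stats::setNames(rep("participatory", 10), sprintf("q%02d", 1:10)))
  seg <- stats::setNames(rep(c("compensated", "improved"), 10), names(pat))
  tab2 <- build_contingency(pat, seg)
  res2 <- run_all_comparisons(tab2)
  expect_false(any(res2$significant))

  holm <- run_all_comparisons(tab, variant = "z_uncorrected",
                              fisher_threshold = 0, adjust = "holm")
  expect_true(all(holm$p_value >= res$p_value))
})
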