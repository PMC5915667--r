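#' Pattern-by-segment counts of the published reference cohort
#'
#' The 231-patient primary-care cohort on which the seven collaboration
#' patterns were originally established, cross-tabulated against the four
#' HbA1c evolution segments (outlier-group row included). Used as a validation
#' fixture: feeding these counts through [build_contingency()] and
#' [run_all_comparisons()] reproduces the reference cohort's reported
#' percentages and subgroup comparisons.
#'
#' @return integer matrix, patterns x segments.
#' @export
reference_cohort_counts <- function() {
  m <- matrix(c(
    30,  3,  4,  4,
    23, 12, 15, 11,
    14,  2,  4,  4,
    17, 10,  7,  1,
     7,  3,  5,  6,
     5,  1,  3,  5,
     5,  2,  4,  6,
    13,  4,  1,  0
  ), ncol = 4, byrow = TRUE,
  dimnames = list(c(PATTERN_LEVELS, "outlier"), SEGMENT_LEVELS))
  m
}

#' Cross-tabulate collaboration patterns against outcome segments
#'
#' @param patterns data frame with `patient_id` and `pattern` columns (as from
#'   [assign_patient_patterns()]), or a named character vector.
#' @param segments data frame with `patient_id` and `segment` columns (as from
#'   [classify_segments()]), or a named character vector.
#' @return object of class `contingency_table`: list with `counts` (matrix,
#'   rows = patterns incl. outliers, columns = the four segments),
#'   `row_totals`, `col_totals`, `total`.
#' @export
build_contingency <- function(patterns, segments) {
  pat <- if (is.data.frame(patterns)) setNames(patterns$pattern, patterns$patient_id)
         else patterns
  seg <- if (is.data.frame(segments)) setNames(segments$segment, segments$patient_id)
         else segments
  only_pat <- setdiff(names(pat), names(seg))
  only_seg <- setdiff(names(seg), names(pat))
  if (length(only_pat) || length(only_seg)) {
    stop("pattern/segment patient sets differ; only in patterns: ",
         paste(only_pat, collapse = ", "), "; only in segments: ",
         paste(only_seg, collapse = ", "))
  }
  seg <- seg[names(pat)]
  row_levels <- c(PATTERN_LEVELS, "unclassified", "outlier")
  unknown <- setdiff(unique(pat), row_levels)
  if (length(unknown)) {
    stop("unknown pattern label(s): ", paste(unknown, collapse = ", "))
  }
  counts <- unclass(table(factor(pat, levels = row_levels),
                          factor(seg, levels = SEGMENT_LEVELS)))
  counts <- counts[rownames(counts) %in% unique(pat), , drop = FALSE]
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), total = sum(counts)),
            class = "contingency_table")
}

#' Row percentages of a contingency table
#'
#' Per-pattern rows are rounded to integer percent; the total row is reported
#' with one decimal.
#'
#' @param tab a `contingency_table`.
#' @return list with `rows` (integer percent matrix) and `total` (one-decimal
#'   percent vector for the pooled cohort).
#' @export
contingency_percentages <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  rows <- round(100 * sweep(tab$counts, 1, pmax(tab$row_totals, 1), "/"))
  total <- round(100 * tab$col_totals / tab$total, 1)
  list(rows = rows, total = total)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Pattern x segment contingency table (", x$total, " patients)\n", sep = "")
  print(cbind(x$counts, total = x$row_totals))
  invisible(x)
}

#' Compare a subgroup proportion with the whole-cohort proportion
#'
#' Two-proportion test of `sub_count/sub_n` against `pop_count/pop_n`,
#' defaulting to the z-test with continuity correction. When the 2 x 2 table
#' of the two samples has a small expected cell (at most `fisher_threshold`),
#' the test switches to the two-sided Fisher exact test. The reference sample
#' is used exactly as given; in the reference analysis it is the *total*
#' cohort, which contains the subgroup (see [run_all_comparisons()] for the
#' complement option).
#'
#' @param sub_count,sub_n successes and size of the subgroup (`sub_n >= 1`).
#' @param pop_count,pop_n successes and size of the reference sample.
#' @param variant `"z"` (continuity-corrected, default) or `"z_uncorrected"`.
#' @param fisher_threshold switch to Fisher when the minimum expected cell is
#'   at most this value (default 5; 0 disables the fallback).
#' @return object of class `proportion_test`: list with `sub_prop`,
#'   `ref_prop`, `method`, `statistic` (signed z, or the Fisher odds ratio)
#'   and `p_value`.
#' @export
compare_to_population <- function(sub_count, sub_n, pop_count, pop_n,
                                  variant = c("z", "z_uncorrected"),
                                  fisher_threshold = 5) {
  variant <- match.arg(variant)
  if (sub_n < 1) stop("sub_n must be at least 1")
  if (sub_count < 0 || sub_count > sub_n || pop_count < 0 || pop_count > pop_n) {
    stop("counts must satisfy 0 <= count <= n")
  }
  tab <- rbind(c(sub_count, sub_n - sub_count),
               c(pop_count, pop_n - pop_count))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) <= fisher_threshold) {
    ft <- fisher.test(tab)
    method <- "Fisher exact"
    statistic <- unname(ft$estimate)
    p <- ft$p.value
  } else {
    pt <- suppressWarnings(
      prop.test(c(sub_count, pop_count), c(sub_n, pop_n),
                correct = variant == "z")
    )
    method <- if (variant == "z") "two-proportion z with continuity correction"
              else "two-proportion z"
    statistic <- sqrt(unname(pt$statistic)) *
      sign(sub_count / sub_n - pop_count / pop_n)
    p <- pt$p.value
  }
  structure(list(sub_prop = sub_count / sub_n, ref_prop = pop_count / pop_n,
                 method = method, statistic = statistic, p_value = p),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("%s: %.1f%% vs %.1f%%, p = %.4f\n", x$method, 100 * x$sub_prop,
              100 * x$ref_prop, x$p_value))
  invisible(x)
}

#' All pattern-by-segment subgroup comparisons
#'
#' One comparison per (non-outlier pattern, segment) pair: the proportion of
#' the pattern's patients in the segment against the same proportion in the
#' reference sample. No multiplicity adjustment is applied by default,
#' mirroring the reference analysis; Holm adjustment is available.
#'
#' @param tab a `contingency_table`.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @inheritParams compare_to_population
#' @param reference `"total"` compares against the whole cohort including the
#'   subgroup (as in the reference analysis); `"complement"` compares against
#'   the remaining patients.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data frame with one row per comparison: `pattern`, `segment`,
#'   `sub_count`, `sub_n`, `sub_pct`, `ref_pct`, `method`, `statistic`,
#'   `p_value`, `significant`.
#' @export
run_all_comparisons <- function(tab, alpha = 0.05,
                                variant = c("z", "z_uncorrected"),
                                fisher_threshold = 5,
                                reference = c("total", "complement"),
                                adjust = c("none", "holm")) {
  stopifnot(inherits(tab, "contingency_table"))
  variant <- match.arg(variant)
  reference <- match.arg(reference)
  adjust <- match.arg(adjust)
  rows <- setdiff(rownames(tab$counts), c("outlier", "unclassified"))
  out <- list()
  for (p in rows) {
    for (s in colnames(tab$counts)) {
      sub_count <- tab$counts[p, s]
      sub_n <- tab$row_totals[[p]]
      if (sub_n == 0) next
      if (reference == "total") {
        ref_count <- tab$col_totals[[s]]
        ref_n <- tab$total
      } else {
        ref_count <- tab$col_totals[[s]] - sub_count
        ref_n <- tab$total - sub_n
      }
      r <- compare_to_population(sub_count, sub_n, ref_count, ref_n,
                                 variant = variant,
                                 fisher_threshold = fisher_threshold)
      out[[length(out) + 1L]] <- data.frame(
        pattern = p, segment = s, sub_count = sub_count, sub_n = sub_n,
        sub_pct = 100 * r$sub_prop, ref_pct = 100 * r$ref_prop,
        method = r$method, statistic = r$statistic, p_value = r$p_value
      )
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (adjust == "holm") res$p_value <- p.adjust(res$p_value, "holm")
  res$significant <- res$p_value <= alpha
  res
}
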