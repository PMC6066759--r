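# Construct/face/content-validity analysis: cohort assignment by DHS
# case count, per-cohort medians, Kruskal-Wallis omnibus, Mann-Whitney U
# post-hoc with a fixed x3 multiplicity correction, percent differences
# between cohort medians, and Likert agreement.
#
# Exact small-sample p-values are computed by full enumeration of
# labelings; ranks use midranks (0.5 credit for ties) throughout.

#' Assign an experience cohort from DHS case count
#'
#' Fewer than 10 dynamic-hip-screw cases -> novice; 10-39 ->
#' intermediate; 40 or more -> expert.
#'
#' @param dhs_count integer vector of completed DHS cases (>= 0).
#' @return A factor with levels `novice`, `intermediate`, `expert`.
#' @export
assign_cohort <- function(dhs_count) {
  ft_assert_finite(dhs_count, "dhs_count")
  if (any(dhs_count < 0))
    ft_stop("dhs_count must be >= 0", "fluorotrack_negative_count")
  factor(ifelse(dhs_count < 10, "novice",
                ifelse(dhs_count < 40, "intermediate", "expert")),
         levels = cohort_levels())
}

cohort_levels <- function() c("novice", "intermediate", "expert")

#' Per-cohort medians of one metric
#'
#' The standard median: midpoint of the two central order statistics for
#' even n.
#'
#' @param records data frame of participant records with a `dhs_count`
#'   or `cohort` column (see [read_cohort_csv()]).
#' @param metric name of the metric column.
#' @return Named numeric vector of medians (novice, intermediate,
#'   expert). An empty cohort raises `fluorotrack_empty_cohort`.
#' @export
cohort_medians <- function(records, metric) {
  cohort <- record_cohorts(records)
  if (!metric %in% names(records))
    ft_stop(sprintf("no column '%s' in records", metric),
            "fluorotrack_invalid_input")
  vapply(cohort_levels(), function(g) {
    v <- records[[metric]][cohort == g]
    if (!length(v))
      ft_stop(sprintf("cohort '%s' is empty", g), "fluorotrack_empty_cohort")
    median(v)
  }, numeric(1))
}

record_cohorts <- function(records) {
  if ("cohort" %in% names(records))
    factor(as.character(records$cohort), levels = cohort_levels())
  else if ("dhs_count" %in% names(records))
    assign_cohort(records$dhs_count)
  else ft_stop("records need a 'cohort' or 'dhs_count' column",
               "fluorotrack_invalid_input")
}

# midranks of pooled values + the tie-correction sum(t^3 - t)
pooled_ranks <- function(x) {
  r <- rank(x)
  t <- table(x)
  list(ranks = r, tie_sum = sum(t^3 - t))
}

kw_statistic <- function(ranks, sizes, tie_sum) {
  n <- length(ranks)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  rs <- vapply(seq_along(sizes),
               function(i) sum(ranks[starts[i]:ends[i]]), numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  corr <- 1 - tie_sum / (n^3 - n)
  if (corr <= 0) return(0)  # all values identical: no evidence, H = 0
  h / corr
}

#' Kruskal-Wallis rank test across cohorts
#'
#' Tie-corrected H on midranks with the chi-square reference
#' distribution on k - 1 degrees of freedom. For small samples (total
#' n <= `exact_max`) an exact permutation p-value is also computed by
#' enumerating every distinct assignment of the pooled observations to
#' groups of the observed sizes.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param exact_max largest total n for which the exact p is enumerated
#'   (default 8).
#' @return A list with `statistic` (H), `raw_p` (chi-square), `exact_p`
#'   (or `NULL`), `df`, and `method = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups, exact_max = 8L) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(!vapply(groups, length, integer(1))))
    ft_stop("need >= 2 non-empty groups", "fluorotrack_insufficient_groups")
  sizes <- vapply(groups, length, integer(1))
  x <- unlist(groups, use.names = FALSE)
  ft_assert_finite(x, "group values")
  n <- length(x)
  if (n < 3L)
    ft_stop("need total n >= 3", "fluorotrack_insufficient_groups")
  pr <- pooled_ranks(x)
  h <- kw_statistic(pr$ranks, sizes, pr$tie_sum)
  df <- length(groups) - 1L
  raw_p <- pchisq(h, df, lower.tail = FALSE)
  exact_p <- NULL
  if (n <= exact_max) {
    hs <- enumerate_group_stats(pr$ranks, sizes,
                                function(r) kw_statistic(r, sizes, pr$tie_sum))
    exact_p <- mean(hs >= h - 1e-9)
  }
  list(statistic = h, raw_p = raw_p, exact_p = exact_p, df = df,
       method = "kruskal_wallis")
}

# Evaluate `stat` on every distinct assignment of `ranks` to groups of
# the given sizes (recursive combination enumeration).
enumerate_group_stats <- function(ranks, sizes, stat) {
  out <- numeric(0)
  recurse <- function(remaining, acc, depth) {
    if (depth > length(sizes)) {
      out[[length(out) + 1L]] <<- stat(acc)
      return(invisible())
    }
    if (depth == length(sizes)) {
      recurse(numeric(0), c(acc, remaining), depth + 1L)
      return(invisible())
    }
    picks <- combn(length(remaining), sizes[depth], simplify = FALSE)
    for (idx in picks)
      recurse(remaining[-idx], c(acc, remaining[idx]), depth + 1L)
    invisible()
  }
  recurse(ranks, numeric(0), 1L)
  out
}

#' Mann-Whitney U test between two cohorts
#'
#' U on midranks (ties receive 0.5 credit). The two-sided p-value is
#' exact -- full enumeration of all `choose(n, n_a)` labelings, counting
#' those at least as far from the null mean `n_a n_b / 2` as observed --
#' when `n_a + n_b <= exact_max`; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max exact-enumeration threshold on total n (default 12;
#'   cohorts of 8/7/11 always take the exact path pairwise).
#' @return A list with `statistic` (`U_a`), `u_b`, `raw_p`, `exact`
#'   (logical), and `method = "mann_whitney"`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b))
    ft_stop("both groups must be non-empty", "fluorotrack_empty_group")
  ft_assert_finite(a, "a"); ft_assert_finite(b, "b")
  na <- length(a); nb <- length(b); n <- na + nb
  pr <- pooled_ranks(c(a, b))
  r <- pr$ranks
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  mu <- na * nb / 2
  if (n <= exact_max) {
    us <- vapply(combn(n, na, simplify = FALSE),
                 function(idx) sum(r[idx]) - na * (na + 1) / 2, numeric(1))
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-9)
    exact <- TRUE
  } else {
    sigma2 <- na * nb / 12 * ((n + 1) - pr$tie_sum / (n * (n - 1)))
    if (sigma2 <= 0) {  # every pooled value tied: no evidence either way
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(statistic = u_a, u_b = u_b, raw_p = p, exact = exact,
       method = "mann_whitney")
}

#' Multiplicity-corrected p-value
#'
#' The study's correction: each post-hoc p-value is multiplied by the
#' number of pairwise comparisons (3) and capped at 1, keeping the alpha
#' cut-off at 0.05.
#'
#' @param raw_p p-value(s) in `[0, 1]`.
#' @param k family size (default 3).
#' @return `min(k * raw_p, 1)`, vectorized.
#' @export
adjust_p <- function(raw_p, k = 3L) {
  ft_assert_finite(raw_p, "raw_p")
  if (any(raw_p < 0 | raw_p > 1))
    ft_stop("raw_p must lie in [0, 1]", "fluorotrack_invalid_input")
  if (k < 1) ft_stop("k must be >= 1", "fluorotrack_invalid_input")
  pmin(k * raw_p, 1)
}

#' Percent difference between two cohort medians
#'
#' `100 * |m1 - m2| / max(m1, m2)`, rounded half-up to an integer -- the
#' larger median is the denominator, so the result is symmetric in its
#' arguments.
#'
#' @param m1,m2 cohort medians (not both zero).
#' @return Integer percent difference.
#' @export
percent_difference <- function(m1, m2) {
  ft_assert_finite(m1, "m1"); ft_assert_finite(m2, "m2")
  if (max(abs(m1), abs(m2)) == 0)
    ft_stop("both medians are zero", "fluorotrack_both_zero")
  as.integer(floor(100 * abs(m1 - m2) / max(m1, m2) + 0.5))
}

#' Likert agreement count and proportion
#'
#' On the 7-point scale a response of 5, 6 or 7 (mildly, moderately or
#' strongly agree) counts as overall agreement.
#'
#' @param responses integer vector of responses in `[1, 7]`.
#' @return A list with `count` (responses >= 5) and `proportion`
#'   (`count / n`).
#' @export
likert_agreement <- function(responses) {
  ft_assert_finite(responses, "responses")
  if (any(responses < 1 | responses > 7 | responses != round(responses)))
    ft_stop("responses must be integers in [1, 7]",
            "fluorotrack_out_of_scale")
  n_agree <- sum(responses >= 5)
  list(count = n_agree, proportion = n_agree / length(responses))
}

#' Full construct/face/content-validity report
#'
#' For each of the five objective metrics: per-cohort medians with the
#' Kruskal-Wallis omnibus p; for each cohort pair: the percent
#' difference between medians and the multiplicity-adjusted (x3,
#' capped) Mann-Whitney p. Likert agreement is tallied per statement
#' column (`q1`..`q4` by default).
#'
#' @param records data frame of participant records (see
#'   [read_cohort_csv()] for the expected columns).
#' @param metrics metric columns to analyze.
#' @param likert_cols Likert statement columns present in `records`.
#' @return A `validity_report` list with data frames `medians` (metric,
#'   per-cohort medians, `kw_h`, `kw_p`), `pairwise` (metric, pair,
#'   `pct_diff`, `mwu_u`, `raw_p`, `adj_p`) and `likert` (statement,
#'   `n_agree`, `n`, `proportion`).
#' @export
validity_report <- function(records,
                            metrics = c("tad_mm", "cor_pct", "time_s",
                                        "n_radiographs", "n_retries"),
                            likert_cols = intersect(paste0("q", 1:4),
                                                    names(records))) {
  cohort <- record_cohorts(records)
  if (any(!cohort_levels() %in% cohort))
    ft_stop("every cohort needs at least one record",
            "fluorotrack_empty_cohort")
  pairs <- list(c("novice", "intermediate"), c("novice", "expert"),
                c("intermediate", "expert"))
  med_rows <- list(); pair_rows <- list()
  for (m in metrics) {
    groups <- lapply(cohort_levels(), function(g) records[[m]][cohort == g])
    names(groups) <- cohort_levels()
    kw <- kruskal_wallis(groups)
    meds <- cohort_medians(records, m)
    med_rows[[m]] <- data.frame(metric = m, novice = meds["novice"],
                                intermediate = meds["intermediate"],
                                expert = meds["expert"],
                                kw_h = kw$statistic, kw_p = kw$raw_p,
                                row.names = NULL)
    for (pr in pairs) {
      pd <- if (max(meds[pr]) == 0) 0L else
        percent_difference(meds[pr[1]], meds[pr[2]])
      mw <- mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]])
      pair_rows[[paste(m, pr[1], pr[2])]] <-
        data.frame(metric = m, pair = paste(pr, collapse = "_vs_"),
                   pct_diff = pd, mwu_u = mw$statistic,
                   raw_p = mw$raw_p, adj_p = adjust_p(mw$raw_p),
                   row.names = NULL)
    }
  }
  likert <- do.call(rbind, lapply(likert_cols, function(q) {
    ag <- likert_agreement(records[[q]])
    data.frame(statement = q, n_agree = ag$count, n = nrow(records),
               proportion = ag$proportion)
  }))
  structure(list(medians = do.call(rbind, med_rows),
                 pairwise = do.call(rbind, pair_rows),
                 likert = likert),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Cohort medians and Kruskal-Wallis omnibus:\n")
  print(x$medians, row.names = FALSE, digits = 4)
  cat("\nPairwise percent differences and adjusted Mann-Whitney p:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  if (!is.null(x$likert) && nrow(x$likert)) {
    cat("\nLikert agreement (score >= 5):\n")
    print(x$likert, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a validity report as JSON
#'
#' @param report a [validity_report()].
#' @param path output JSON file.
#' @export
write_validity_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA,
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Read a participant cohort CSV
#'
#' Expected header: `id,dhs_count,pgy,tad_mm,cor_pct,time_s,
#' n_radiographs,n_retries,q1,q2,q3,q4`. A `cohort` factor column is
#' appended from `dhs_count`.
#'
#' @param path CSV file.
#' @return A data frame of participant records.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$cohort <- assign_cohort(df$dhs_count)
  df
}
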