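#' Mann-Whitney U comparison of two samples
#'
#' Rank-sum comparison with midrank tie handling. The two-sided p-value is
#' exact (full enumeration) when the combined sample size is at most
#' `exact_max` and there are no ties; otherwise the normal approximation with
#' tie and continuity correction is used. The reported `statistic` is
#' `min(U_a, U_b)` (the convention is stated in `method`); quartiles use
#' linear interpolation between order statistics.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param exact_max Largest combined sample size for which the exact
#'   enumeration p-value is used (default 12).
#' @param exact Override the exact/approximate choice (`TRUE`/`FALSE`);
#'   `NULL` (default) applies the rule above.
#' @return A one-row tibble: group sizes, medians and quartiles, `statistic`
#'   (min-U), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mann_whitney <- function(a, b, exact_max = 12, exact = NULL) {
  a <- as.double(a[!is.na(a)])
  b <- as.double(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) {
    abort("insufficient group size: each group needs at least 2 observations")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- exact %||% (!ties && length(a) + length(b) <= exact_max)
  if (use_exact && ties) {
    warn("ties present: falling back to the corrected normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, conf.int = FALSE)
  )
  u_a <- unname(wt$statistic)
  u_min <- min(u_a, length(a) * length(b) - u_a)
  qs <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  qa <- qs(a); qb <- qs(b)
  tibble(
    n_a = length(a), n_b = length(b),
    median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
    median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
    statistic = u_min,
    p_value = wt$p.value,
    method = if (use_exact) "Mann-Whitney U (exact, min-U convention)"
             else "Mann-Whitney U (normal approx., tie + continuity correction, min-U convention)"
  )
}

#' Spearman rank correlation of paired samples
#'
#' Rho is the Pearson correlation of midranks. The two-sided p-value is
#' exact (permutation distribution) for `n <= exact_max` without ties, and
#' uses the t approximation otherwise. Pairs with a missing value are
#' dropped and counted.
#'
#' @param x,y Paired numeric vectors (at least 4 complete pairs).
#' @param exact_max Largest n for which the exact permutation p-value is
#'   used (default 7).
#' @return A one-row tibble: `rho`, `p_value`, `n_used`, `n_dropped`,
#'   `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 7) {
  if (length(x) != length(y)) abort("`x` and `y` must be the same length")
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  x <- as.double(x[ok]); y <- as.double(y[ok])
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("undefined correlation: zero rank variance")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- !ties && n <= exact_max
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = use_exact)
  )
  tibble(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    n_used = n,
    n_dropped = n_dropped,
    method = if (use_exact) "Spearman rho (exact permutation)"
             else "Spearman rho (t approximation, midranks)"
  )
}

#' Compare a 2 x k contingency table
#'
#' Pearson chi-square without continuity correction by default; for 2 x 2
#' tables with any expected cell below 5 the Fisher exact test (two-sided by
#' the point-probability rule) is used instead. The choice is reported in
#' `method`.
#'
#' @param tab A matrix of nonnegative integer counts with 2 rows.
#' @param method `"auto"` (the rule above), `"chisq"` or `"fisher"` (the
#'   latter only for 2 x 2 tables).
#' @return A one-row tibble: `statistic` (chi-square; `NA` for Fisher),
#'   `df`, `p_value`, `method`.
#' @export
compare_categorical <- function(tab, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) abort("`tab` must have exactly 2 rows")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin: a row or column of `tab` is empty")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (all(dim(tab) == 2) && any(expected < 5)) "fisher" else "chisq"
  }
  if (method == "fisher") {
    if (!all(dim(tab) == 2)) abort("Fisher exact test here supports 2 x 2 tables only")
    ft <- fisher.test(tab)
    tibble(statistic = NA_real_, df = NA_integer_, p_value = ft$p.value,
           method = "Fisher exact (two-sided, point-probability rule)")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(statistic = unname(ct$statistic), df = as.integer(ct$parameter),
           p_value = ct$p.value,
           method = "Pearson chi-square (no continuity correction)")
  }
}

#' Shapiro-Wilk normality screen
#'
#' Annotates a sample with the Shapiro-Wilk W and p-value. In this pipeline
#' normality screening is descriptive only: group comparisons stay
#' nonparametric regardless of the outcome.
#'
#' @param x Numeric sample, 3 <= n <= 5000, not constant.
#' @return A one-row tibble: `n`, `statistic` (W), `p_value`.
#' @export
normality_screen <- function(x) {
  x <- as.double(x[!is.na(x)])
  if (length(x) < 3) abort("not applicable: Shapiro-Wilk needs n >= 3")
  if (diff(range(x)) < 1e-24) abort("not applicable: constant sample")
  sw <- shapiro.test(x)
  tibble(n = length(x), statistic = unname(sw$statistic), p_value = sw$p.value)
}

rar_variables <- c(
  is = "Interdaily stability",
  iv = "Intradaily variability",
  ra = "Relative amplitude",
  m10 = "Most active 10 continuous hours",
  l5 = "Least active 5 continuous hours"
)

#' Two-group study analysis of rest-activity rhythm metrics
#'
#' Reproduces the cohort-level analysis layer on a flat per-participant
#' table: a comparison block (per-group median and IQR of IS, IV, RA, M10,
#' L5, with Mann-Whitney two-sided p-values), a normality screen per metric,
#' and a correlation block (Spearman rho of Barthel Index against every
#' metric over all participants, and of 4AT against every metric over the
#' participants to whom the 4AT was administered). No multiplicity
#' adjustment is applied by default; `adjust = "holm"` is available.
#'
#' @param cohort Data frame with columns `participant_id`, `group` (exactly
#'   two levels, each with >= 2 participants), `barthel_index`, `four_at`
#'   (may be `NA`), and the metric columns `is`, `iv`, `m10`, `l5`, `ra`.
#'   Built by [compute_cohort_metrics()] or joined from CSVs.
#' @param alpha Significance threshold used for flagging (default 0.05).
#' @param adjust `"none"` (default, mirroring the unadjusted design) or
#'   `"holm"`, applied within each block.
#' @return An object of class `rar_study`: a list with tibbles `comparison`,
#'   `normality` and `correlations`, plus `alpha`, `adjust`, `groups` and
#'   group sizes. Has [tidy()], [glance()], `print()` and [autoplot()]
#'   methods.
#' @export
run_study <- function(cohort, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  need <- c("participant_id", "group", "barthel_index", "four_at",
            names(rar_variables))
  missing_c <- setdiff(need, names(cohort))
  if (length(missing_c)) {
    abort(sprintf("`cohort` is missing columns: %s",
                  paste(missing_c, collapse = ", ")))
  }
  if (anyDuplicated(cohort$participant_id)) abort("duplicated participant_id")
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) abort("`cohort` must contain exactly two groups")
  n_g <- table(factor(cohort$group, levels = groups))
  if (any(n_g < 2)) {
    abort("insufficient group size: each group needs at least 2 participants")
  }
  comparison <- purrr::map(names(rar_variables), function(v) {
    res <- mann_whitney(cohort[[v]][cohort$group == groups[1]],
                        cohort[[v]][cohort$group == groups[2]])
    dplyr::bind_cols(tibble(variable = v, label = rar_variables[[v]]), res)
  }) |> dplyr::bind_rows()
  normality <- purrr::map(names(rar_variables), function(v) {
    res <- tryCatch(normality_screen(cohort[[v]]),
                    error = function(e) tibble(n = NA_integer_,
                                               statistic = NA_real_,
                                               p_value = NA_real_))
    dplyr::bind_cols(tibble(variable = v), res)
  }) |> dplyr::bind_rows()
  cor_block <- function(score, data) {
    purrr::map(names(rar_variables), function(v) {
      res <- spearman_cor(data[[score]], data[[v]])
      dplyr::bind_cols(tibble(score = score, variable = v), res)
    }) |> dplyr::bind_rows()
  }
  has_4at <- !is.na(cohort$four_at)
  correlations <- dplyr::bind_rows(
    cor_block("barthel_index", cohort),
    if (sum(has_4at) >= 4) cor_block("four_at", cohort[has_4at, , drop = FALSE])
  )
  comparison$p_adjusted <- p.adjust(comparison$p_value, method = adjust)
  comparison$significant <- comparison$p_adjusted < alpha
  correlations$p_adjusted <- stats::ave(
    correlations$p_value, correlations$score,
    FUN = function(p) p.adjust(p, method = adjust)
  )
  correlations$significant <- correlations$p_adjusted < alpha
  structure(
    list(comparison = comparison, normality = normality,
         correlations = correlations,
         alpha = alpha, adjust = adjust,
         groups = groups, n = as.integer(n_g)),
    class = "rar_study"
  )
}

#' @export
print.rar_study <- function(x, digits = 2, ...) {
  cat(sprintf("Rest-activity rhythm study: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  cat(sprintf("alpha = %.3g, adjustment: %s\n\n", x$alpha, x$adjust))
  fmt <- function(m, q1, q3) sprintf("%.*f (%.*f-%.*f)", digits, m, digits, q1, digits, q3)
  cat("Group comparison (median (IQR), Mann-Whitney U):\n")
  with(x$comparison, {
    for (i in seq_along(variable)) {
      cat(sprintf("  %-32s %-20s %-20s p=%.3g%s\n", label[i],
                  fmt(median_a[i], q1_a[i], q3_a[i]),
                  fmt(median_b[i], q1_b[i], q3_b[i]),
                  p_value[i], ifelse(significant[i], " *", "")))
    }
  })
  cat("\nSpearman correlations with clinical scores:\n")
  with(x$correlations, {
    for (i in seq_along(variable)) {
      cat(sprintf("  %-14s ~ %-4s rho=%+.2f  p=%.3g  (n=%d)%s\n",
                  score[i], variable[i], rho[i], p_value[i], n_used[i],
                  ifelse(significant[i], " *", "")))
    }
  })
  if (x$adjust == "none") {
    cat("\nNote: p-values are unadjusted for multiplicity.\n")
  }
  invisible(x)
}

#' @rdname run_study
#' @param x A `rar_study` object.
#' @param block Which table to return: `"comparison"` (default),
#'   `"correlations"` or `"normality"`.
#' @param ... Unused.
#' @method tidy rar_study
#' @export
tidy.rar_study <- function(x, block = c("comparison", "correlations", "normality"),
                           ...) {
  block <- match.arg(block)
  x[[block]]
}

#' @rdname run_study
#' @method glance rar_study
#' @export
glance.rar_study <- function(x, ...) {
  tibble(
    n_a = x$n[1], n_b = x$n[2],
    group_a = x$groups[1], group_b = x$groups[2],
    alpha = x$alpha, adjust = x$adjust,
    n_comparisons_significant = sum(x$comparison$significant),
    n_correlations_significant = sum(x$correlations$significant)
  )
}

#' Rest-activity metrics for every participant of a simulated cohort
#'
#' Runs [rar_metrics()] over the `epochs` list-column of a
#' [simulate_cohort()] table and returns the flat per-participant table that
#' [run_study()] consumes.
#'
#' @param cohort A [simulate_cohort()] tibble (or any tibble with an
#'   `epochs` list-column of minute-epoch tibbles).
#' @inheritParams rar_metrics
#' @return The input tibble without `epochs`, with columns `is`, `iv`,
#'   `m10`, `l5`, `ra`, `n_days_used` appended.
#' @export
compute_cohort_metrics <- function(cohort, min_days = 7,
                                   min_valid_minutes = 45, wrap = FALSE,
                                   resolution = "minute") {
  stopifnot(is.data.frame(cohort), "epochs" %in% names(cohort))
  ms <- lapply(cohort$epochs, function(e) {
    m <- rar_metrics(e, min_days = min_days,
                     min_valid_minutes = min_valid_minutes,
                     wrap = wrap, resolution = resolution)
    c(m$is, m$iv, m$m10, m$l5, m$ra, m$n_days_used)
  })
  mm <- do.call(rbind, ms)
  out <- cohort[, setdiff(names(cohort), "epochs"), drop = FALSE]
  out$is <- mm[, 1]
  out$iv <- mm[, 2]
  out$m10 <- mm[, 3]
  out$l5 <- mm[, 4]
  out$ra <- mm[, 5]
  out$n_days_used <- as.integer(mm[, 6])
  out
}
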