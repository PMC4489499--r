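# Group-difference analysis over per-session metrics tables: Welch t-test
# on means, Wilcoxon rank-sum on medians, scanned over every metric and
# task scope.

#' Aggregate session records into a cohort frame
#'
#' Computes the metrics table of every session and joins the session
#' metadata, yielding one row per (subject, task) with the flattened
#' metric columns of [metrics_row()].
#'
#' @param records List of `session_record`s sharing a studio
#'   configuration.
#' @return Data frame with columns `subject`, `task`, one column per group
#'   label, and the metric columns.
#' @export
aggregate_sessions <- function(records) {
  if (length(records) == 0L)
    return(data.frame(subject = character(0), task = character(0)))
  keys <- vapply(records, function(r) paste(r$meta$subject, r$meta$task), "")
  if (anyDuplicated(keys))
    stop("duplicate (subject, task) pair: ", keys[anyDuplicated(keys)])
  pal0 <- records[[1]]$config$palette
  tool0 <- records[[1]]$config$toolset
  rows <- lapply(records, function(r) {
    if (!identical(r$config$palette, pal0) || !identical(r$config$toolset, tool0))
      stop("all sessions must share the studio configuration")
    m <- metrics_row(compute_metrics(r))
    meta_cols <- c(list(subject = r$meta$subject, task = r$meta$task),
                   r$meta$groups)
    cbind(as.data.frame(meta_cols, stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Welch t-test and Wilcoxon rank-sum on the same two samples.  The
# rank-sum test is exact when the combined sample size is <= 20 and there
# are no ties, otherwise it uses the normal approximation with tie and
# continuity correction.  Both-groups-constant data are degenerate: the
# t-test reports p = 1 when the means agree (p = 0 otherwise).
two_group_test <- function(x, y) {
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    t_stat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    p_t <- if (mean(x) == mean(y)) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    p_t <- tt$p.value
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(t_stat = t_stat, p_t = p_t,
       w_stat = unname(wt$statistic), p_w = wt$p.value,
       degenerate = degenerate)
}

#' Compare one metric between two groups
#'
#' Tests the group difference of a metric with the two-test convention:
#' a two-sided Welch t-test for the means and a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test for the medians, each flagged for
#' significance at `alpha`, plus the joint "significant under both tests"
#' flag.  Group means are reported with their standard errors.
#'
#' @param frame Cohort frame from [aggregate_sessions()] (or any data
#'   frame with the metric and grouping columns).
#' @param metric Name of the numeric metric column.
#' @param group_label Name of the grouping column; exactly two groups must
#'   be present in scope.
#' @param scope Optional character vector of task labels to restrict to
#'   (requires a `task` column); `NULL` pools all rows.
#' @param alpha Significance level.
#' @return A one-row data frame (class `cohort_result`) with group sizes,
#'   means, SEMs, medians, both test statistics and p-values, and
#'   significance flags.  Groups smaller than 2 yield `NA` statistics
#'   rather than an error.
#' @export
compare_groups <- function(frame, metric, group_label, scope = NULL,
                           alpha = 0.05) {
  if (!metric %in% names(frame)) stop("no such metric column: ", metric)
  if (!group_label %in% names(frame)) stop("no such group column: ", group_label)
  if (!is.null(scope)) frame <- frame[frame$task %in% scope, , drop = FALSE]
  g <- factor(frame[[group_label]])
  lev <- levels(droplevels(g))
  if (length(lev) != 2L)
    stop("exactly two groups required in scope; found ", length(lev))
  x <- frame[[metric]][g == lev[1]]
  y <- frame[[metric]][g == lev[2]]
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  base <- data.frame(
    metric = metric,
    scope = if (is.null(scope)) "pooled" else paste(scope, collapse = "+"),
    group1 = lev[1], group2 = lev[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), sem1 = sem(x), median1 = stats::median(x),
    mean2 = mean(y), sem2 = sem(y), median2 = stats::median(y),
    stringsAsFactors = FALSE)
  if (length(x) < 2L || length(y) < 2L) {
    res <- cbind(base, data.frame(t_stat = NA_real_, p_t = NA_real_,
                                  w_stat = NA_real_, p_w = NA_real_,
                                  sig_t = NA, sig_w = NA, sig_both = NA,
                                  degenerate = TRUE))
  } else {
    ts <- two_group_test(x, y)
    res <- cbind(base, data.frame(t_stat = ts$t_stat, p_t = ts$p_t,
                                  w_stat = ts$w_stat, p_w = ts$p_w,
                                  sig_t = ts$p_t < alpha,
                                  sig_w = ts$p_w < alpha,
                                  sig_both = ts$p_t < alpha && ts$p_w < alpha,
                                  degenerate = ts$degenerate))
  }
  class(res) <- c("cohort_result", "data.frame")
  res
}

#' Scan every metric (and scope) for group differences
#'
#' Runs [compare_groups()] for each metric column over each scope and
#' stacks the results.  P-values are raw by default; `adjust = "BH"` adds
#' Benjamini-Hochberg adjusted columns (`p_t_adj`, `p_w_adj`) as a clearly
#' separate extension of the raw report.
#'
#' @param frame Cohort frame.
#' @param group_label Grouping column name.
#' @param metrics Metric column names; defaults to all numeric columns
#'   that are not metadata.
#' @param scopes List of scopes (each `NULL` for pooled, or a character
#'   vector of tasks).  Defaults to pooled only.
#' @param alpha Significance level.
#' @param adjust `"none"` (default, matching the raw-p reporting
#'   convention) or `"BH"`.
#' @return Data frame of stacked `cohort_result` rows; the subset with
#'   `sig_both` is the headline "significant under both tests" set.
#' @export
scan_metrics <- function(frame, group_label, metrics = NULL,
                         scopes = list(NULL), alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(metrics)) {
    meta_cols <- c("subject", "task", group_label)
    metrics <- names(frame)[vapply(frame, is.numeric, TRUE)]
    metrics <- setdiff(metrics, meta_cols)
  }
  res <- list()
  for (sc in scopes)
    for (m in metrics)
      res[[length(res) + 1L]] <- compare_groups(frame, m, group_label,
                                                scope = sc, alpha = alpha)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_t_adj <- stats::p.adjust(out$p_t, method = "BH")
    out$p_w_adj <- stats::p.adjust(out$p_w, method = "BH")
    out$sig_both_adj <- out$p_t_adj < alpha & out$p_w_adj < alpha
  }
  out
}
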