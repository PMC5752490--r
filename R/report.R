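# Group-comparison statistics and summary tables over per-spheroid
# measurement tables. P-values are reported unadjusted (no multiple-testing
# correction is applied); significance is declared at alpha = 0.05.

#' Compare a metric between spheroid groups
#'
#' Runs the chosen design on per-spheroid values:
#' * `"t"` — Welch two-sample t-test,
#' * `"paired-t"` — paired t-test (values matched on `id` across the two
#'   groups),
#' * `"anova"` — one-way ANOVA over >= 2 groups,
#' * `"wilcoxon"` — Wilcoxon rank-sum,
#' * `"kruskal"` — Kruskal-Wallis over >= 2 groups.
#'
#' With `design = NULL` the test is chosen by a simple size rule: a
#' nonparametric test (Wilcoxon for 2 groups, Kruskal-Wallis otherwise) when
#' any group has n < 20, else the parametric counterpart.
#'
#' Degenerate identical groups (zero between- and within-difference) are
#' reported with statistic 0 and p = 1 rather than an error.
#'
#' @param values numeric measurements.
#' @param group group label per measurement (>= 2 groups).
#' @param design test design, or `NULL` for the size-based default.
#' @param id spheroid ids, required for `"paired-t"` (each id must appear
#'   exactly once per group).
#' @param alpha significance level.
#' @return list of class `comparison_result`: `metric` test name, per-group
#'   `n`, `means`, `sds`, `statistic`, `p_value` (unadjusted), `significant`.
#' @export
compare_groups <- function(values, group,
                           design = c("t", "paired-t", "anova", "wilcoxon",
                                      "kruskal"),
                           id = NULL, alpha = 0.05) {
  group <- factor(group)
  ng <- nlevels(group)
  if (ng < 2) stop("need at least 2 groups")
  if (is.null(design)) {
    small <- any(table(group) < 20)
    design <- if (ng == 2) (if (small) "wilcoxon" else "t")
              else (if (small) "kruskal" else "anova")
  } else design <- match.arg(design)
  if (design %in% c("t", "paired-t", "wilcoxon") && ng != 2)
    stop(sprintf("design '%s' requires exactly 2 groups", design))
  split_v <- split(values, group)
  a <- split_v[[1]]; b <- if (ng >= 2) split_v[[2]] else NULL
  res <- switch(design,
    "t" = {
      if (isTRUE(all.equal(a, b)) && stats::var(a) == 0)
        list(stat = 0, p = 1, name = "Two-sample t-test")
      else {
        tt <- stats::t.test(a, b)
        list(stat = unname(tt$statistic), p = tt$p.value,
             name = "Welch two-sample t-test")
      }
    },
    "paired-t" = {
      if (is.null(id)) stop("paired design requires 'id'")
      ids <- split(id, group)
      if (!setequal(ids[[1]], ids[[2]]) ||
          anyDuplicated(ids[[1]]) || anyDuplicated(ids[[2]]))
        stop("paired design requires each id exactly once per group")
      b_m <- b[match(ids[[1]], ids[[2]])]
      d <- a - b_m
      if (stats::var(d) == 0) {
        # constant difference: zero-variance shift, p -> 0 unless shift 0
        if (all(d == 0)) list(stat = 0, p = 1, name = "Paired t-test")
        else list(stat = sign(mean(d)) * Inf, p = 0, name = "Paired t-test")
      } else {
        tt <- stats::t.test(a, b_m, paired = TRUE)
        list(stat = unname(tt$statistic), p = tt$p.value,
             name = "Paired t-test")
      }
    },
    "anova" = {
      if (all(vapply(split_v, stats::var, numeric(1)) == 0) &&
          length(unique(vapply(split_v, mean, numeric(1)))) == 1)
        list(stat = 0, p = 1, name = "One-way ANOVA")
      else {
        fit <- stats::aov(values ~ group)
        s <- summary(fit)[[1]]
        list(stat = s[["F value"]][1], p = s[["Pr(>F)"]][1],
             name = "One-way ANOVA")
      }
    },
    "wilcoxon" = {
      if (identical(sort(a), sort(b)))
        list(stat = NA_real_, p = 1, name = "Wilcoxon rank sum")
      else {
        wt <- stats::wilcox.test(a, b, exact = FALSE)
        list(stat = unname(wt$statistic), p = wt$p.value, name = wt$method)
      }
    },
    "kruskal" = {
      kt <- stats::kruskal.test(values, group)
      list(stat = unname(kt$statistic), p = kt$p.value, name = kt$method)
    })
  structure(list(
    metric = res$name, design = design, groups = levels(group),
    n = vapply(split_v, length, integer(1)),
    means = vapply(split_v, mean, numeric(1)),
    sds = vapply(split_v, function(v)
      if (length(v) > 1) stats::sd(v) else 0, numeric(1)),
    statistic = res$stat, p_value = res$p,
    significant = res$p < alpha, alpha = alpha,
    p_adjusted = FALSE), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic %.4g, p = %.4g%s [unadjusted]\n",
              x$metric, paste(x$groups, collapse = " vs "),
              x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Condition x metric summary of a per-spheroid table
#'
#' One row per (condition, metric): n, mean, SD and — for metrics with a
#' matching `<metric>_positive` logical column — the positive fraction.
#' Single-observation groups get SD 0 with `sd_defined = FALSE`. Row order
#' is deterministic (condition, then metric, alphabetical) and invariant to
#' the input row order.
#'
#' @param table data.frame of per-spheroid measurements.
#' @param condition name of the condition-label column.
#' @param metrics character vector of numeric metric columns; default: all
#'   numeric columns except `condition`.
#' @return summary data.frame.
#' @export
summarize_spheroids <- function(table, condition = "condition",
                                metrics = NULL) {
  if (!nrow(table)) stop("empty table")
  if (!condition %in% names(table))
    stop(sprintf("no '%s' column", condition))
  if (is.null(metrics))
    metrics <- sort(setdiff(names(table)[vapply(table, is.numeric,
                                                logical(1))], condition))
  conds <- sort(unique(as.character(table[[condition]])))
  rows <- list()
  for (cn in conds) {
    sub <- table[table[[condition]] == cn, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      pos_col <- paste0(m, "_positive")
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, metric = m, n = length(v),
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        sd_defined = length(v) > 1,
        positive_fraction = if (pos_col %in% names(sub))
          mean(sub[[pos_col]]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
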