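## Group-level statistics across samples/populations: mean +/- SD, fold
## changes, unpaired two-tailed t tests, HDR/NHEJ-ratio tables.

#' Tag an outcome table with sample metadata
#'
#' @param outcome an [quantify()] result.
#' @param sample sample identifier.
#' @param population population label (e.g. HSC, MPP, progenitor, G0).
#' @param condition condition label (e.g. "SC SC", "SC XRC").
#' @param replicate donor/replicate identifier.
#' @return one-row data.frame combining metadata with the outcome metrics.
#' @export
sample_outcome <- function(outcome, sample, population = "all",
                           condition = "none", replicate = "1") {
  stopifnot(inherits(outcome, "outcome_table"))
  if (!nzchar(population) || !nzchar(condition))
    stop("labels must be non-empty")
  cbind(data.frame(sample = sample, population = population,
                   condition = condition, replicate = as.character(replicate),
                   stringsAsFactors = FALSE),
        as.data.frame(outcome))
}

#' Summarize a metric across a group of samples
#'
#' Sample mean and sample SD (n-1 denominator). Undefined values (e.g.
#' HDR/NHEJ ratios with zero NHEJ reads) are excluded and counted.
#'
#' @param values numeric vector of the metric across samples.
#' @param group group label for the output row.
#' @param metric metric name.
#' @return one-row data.frame: `group`, `metric`, `n`, `mean`, `sd`
#'   (`NA` for n < 2), `n_excluded`.
#' @export
summarize_group <- function(values, group = "group", metric = "hdr_rate") {
  excl <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("empty group (all values undefined)")
  data.frame(group = group, metric = metric, n = length(v), mean = mean(v),
             sd = if (length(v) >= 2L) sd(v) else NA_real_,
             n_excluded = excl, stringsAsFactors = FALSE)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare two groups of samples
#'
#' Unpaired two-tailed t test (pooled variance by default, the classic
#' "unpaired t test"; set `var_equal = FALSE` for Welch) plus the fold
#' change of group means, `mean(a) / mean(b)`.
#'
#' @param a,b numeric vectors of a shared metric for the two groups.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return list: `fold_change`, `t_statistic`, `df`, `p_value`,
#'   `significance` (stars at 0.05/0.01/0.001), `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `test` ("student"/"welch"/"skipped").
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  fold <- if (mean(b) > 0) mean(a) / mean(b) else NA_real_
  if (length(a) < 2L || length(b) < 2L) {
    return(list(fold_change = fold, t_statistic = NA_real_, df = NA_real_,
                p_value = NA_real_, significance = NA_character_,
                n_a = length(a), n_b = length(b),
                mean_a = mean(a), mean_b = mean(b),
                test = "skipped", reason = "group with n < 2"))
  }
  tt <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(fold_change = fold, t_statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value,
       significance = significance_stars(tt$p.value),
       n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b),
       test = if (var_equal) "student" else "welch")
}

#' Per-group HDR/NHEJ ratio table with pairwise fold changes
#'
#' @param samples data.frame of tagged sample outcomes (rows from
#'   [sample_outcome()], or any data.frame with the metric column and the
#'   grouping column).
#' @param group_by grouping column name (default `"condition"`).
#' @param metric metric column (default `"hdr_nhej_ratio"`).
#' @param var_equal see [compare_groups()].
#' @return list with `summaries` (one [summarize_group()] row per group) and
#'   `comparisons` (all pairwise rows: `group_a`, `group_b`, `fold_change`,
#'   `t_statistic`, `df`, `p_value`, `significance`); `comparisons` is empty
#'   with a single group.
#' @export
ratio_table <- function(samples, group_by = "condition",
                        metric = "hdr_nhej_ratio", var_equal = TRUE) {
  stopifnot(is.data.frame(samples), group_by %in% names(samples),
            metric %in% names(samples))
  groups <- split(samples[[metric]], samples[[group_by]])
  if (any(vapply(groups, function(v) all(is.na(v)), logical(1))))
    stop("group with all-undefined ", metric)
  summaries <- do.call(rbind, lapply(names(groups), function(g)
    summarize_group(groups[[g]], group = g, metric = metric)))
  comps <- list()
  gn <- names(groups)
  if (length(gn) > 1L) {
    for (i in seq_along(gn)) for (j in seq_along(gn)) {
      if (i >= j) next
      cc <- compare_groups(groups[[i]], groups[[j]], var_equal = var_equal)
      comps[[length(comps) + 1L]] <- data.frame(
        group_a = gn[i], group_b = gn[j], fold_change = cc$fold_change,
        t_statistic = cc$t_statistic, df = cc$df, p_value = cc$p_value,
        significance = if (is.na(cc$p_value)) NA_character_ else cc$significance,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame(group_a = character(0), group_b = character(0),
               fold_change = numeric(0), t_statistic = numeric(0),
               df = numeric(0), p_value = numeric(0),
               significance = character(0), stringsAsFactors = FALSE)
  list(summaries = summaries, comparisons = comparisons)
}
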