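## Group summaries and significance testing: unpaired two-tailed t tests
## (Welch by default, Student's pooled-variance behind a flag) with
## Holm-Bonferroni adjustment across an explicit comparison family.

#' Per-group mean, SE and n
#'
#' @param values Numeric vector of a metric (NA allowed; dropped with a
#'   count).
#' @param groups Group label per value.
#' @return Data frame with columns `group`, `n`, `mean`, `se` (SE is the
#'   sample SD over sqrt(n); `NA` at n = 1), `n_missing`.
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  out <- lapply(split(values, factor(groups, levels = unique(groups))),
                function(v) {
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v)) stop_flagwave("empty group", "flagwave_stats_error")
    data.frame(n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n_missing = miss)
  })
  df <- do.call(rbind, out)
  cbind(data.frame(group = rownames(df), stringsAsFactors = FALSE),
        df, row.names = NULL)
}

#' Unpaired two-tailed t test
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom by default; `var_equal = TRUE` gives Student's pooled-variance
#' test. Two identical constant groups return `t = 0, p = 1` by
#' convention.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Use the pooled-variance test.
#' @return List with `t_stat`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `se_a`, `se_b`, `n_a`, `n_b`.
#' @export
t_test_unpaired <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    stop_flagwave("each group needs n >= 2", "flagwave_stats_error")
  }
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t <- 0; p <- 1; df <- na + nb - 2
    } else {
      t <- sign(ma - mb) * Inf; p <- 0; df <- na + nb - 2
    }
  } else {
    if (var_equal) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    t <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t_stat = t, df = df, p_value = p, mean_a = ma, mean_b = mb,
       se_a = stats::sd(a) / sqrt(na), se_b = stats::sd(b) / sqrt(nb),
       n_a = na, n_b = nb)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down adjustment: with the p-values sorted ascending, the i-th
#' adjusted value is `max_{j <= i} min(1, (m - j + 1) * p_(j))`; results are
#' returned in the original order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop_flagwave("p-values must lie in (0, 1]", "flagwave_stats_error")
  }
  m <- length(p_values)
  o <- order(p_values)
  adj <- pmin(1, (m - seq_len(m) + 1) * p_values[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare groups of per-flagellum results
#'
#' Runs an unpaired t test for each listed pair of groups and adjusts the
#' p-values by Holm-Bonferroni across the listed pairs only (the explicit
#' comparison family, not all pairwise).
#'
#' @param results Data frame of per-flagellum results (e.g. from
#'   [read_results()] or [results_to_df()]).
#' @param metric Column name of the metric to compare.
#' @param comparisons List of length-2 character vectors of group labels,
#'   or a single string `"A=B,C=D"`.
#' @param group_col Column holding the group label (default `"group"`; if
#'   absent, `genotype:condition` is constructed).
#' @param alpha Significance level.
#' @param var_equal Use Student's pooled-variance test.
#' @return Data frame with one row per comparison: group labels, n, means,
#'   SEs, `t_stat`, `p_raw`, `p_adjusted`, `significant`.
#' @export
compare_groups <- function(results, metric, comparisons,
                           group_col = "group", alpha = 0.05,
                           var_equal = FALSE) {
  if (!group_col %in% names(results)) {
    if (all(c("genotype", "condition") %in% names(results))) {
      results[[group_col]] <- paste(results$genotype, results$condition,
                                    sep = ":")
    } else {
      stop_flagwave("no group column in results", "flagwave_stats_error")
    }
  }
  if (!metric %in% names(results)) {
    stop_flagwave(sprintf("metric '%s' absent from results", metric),
                  "flagwave_stats_error")
  }
  if (is.character(comparisons) && length(comparisons) == 1L) {
    comparisons <- strsplit(strsplit(comparisons, ",")[[1]], "=")
  }
  vals <- split(results[[metric]], results[[group_col]])
  rows <- lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2)
    for (g in pair) {
      if (!g %in% names(vals)) {
        stop_flagwave(sprintf("unknown group '%s'", g),
                      "flagwave_stats_error")
      }
    }
    tt <- t_test_unpaired(vals[[pair[1]]], vals[[pair[2]]],
                          var_equal = var_equal)
    data.frame(group_a = pair[1], group_b = pair[2],
               n_a = tt$n_a, n_b = tt$n_b,
               mean_a = tt$mean_a, mean_b = tt$mean_b,
               se_a = tt$se_a, se_b = tt$se_b,
               t_stat = tt$t_stat, p_raw = tt$p_value,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$p_adjusted <- holm_bonferroni(pmax(df$p_raw, .Machine$double.xmin))
  df$significant <- df$p_adjusted < alpha
  df
}
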