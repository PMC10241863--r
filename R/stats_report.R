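## Group statistics and report assembly.
##
## The experimental comparisons are two-tailed t-tests between day/condition
## groups and one-way ANOVA across multi-group panels. Welch's t-test is
## the default (the group SDs of these measurements differ visibly); a
## pooled-variance mode is available. No multiple-testing correction is
## applied; the report records the number of comparisons made.

check_group_table <- function(table, metric, group_col) {
  if (!metric %in% names(table))
    vm_abort(sprintf("metric column '%s' not found", metric),
             "vitmech_domain_error")
  if (!group_col %in% names(table))
    vm_abort(sprintf("group column '%s' not found", group_col),
             "vitmech_domain_error")
  if (any(is.na(table[[metric]])))
    vm_abort("compared metric column contains missing values",
             "vitmech_domain_error")
  invisible(TRUE)
}

#' Two-sample two-tailed t-test between groups
#'
#' @param table Data frame with one row per sample.
#' @param metric Name of the numeric column to compare.
#' @param group_a,group_b Group labels to compare.
#' @param group_col Name of the group label column (default `"group"`).
#' @param equal_var Use the pooled-variance (classic) t-test instead of
#'   Welch's (default `FALSE`).
#' @return Data frame row: `metric, group_a, group_b, n_a, n_b, mean_a,
#'   sd_a, mean_b, sd_b, t, df, p`.
#'
#' Errors: `vitmech_insufficient_data` if either group has fewer than 2
#' values.
#' @examples
#' tab <- data.frame(group = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' two_sample_test(tab, "y", "a", "b", equal_var = TRUE)
#' @export
two_sample_test <- function(table, metric, group_a, group_b,
                            group_col = "group", equal_var = FALSE) {
  check_group_table(table, metric, group_col)
  xa <- table[[metric]][table[[group_col]] == group_a]
  xb <- table[[metric]][table[[group_col]] == group_b]
  if (length(xa) < 2L || length(xb) < 2L)
    vm_abort("each group needs at least 2 values",
             "vitmech_insufficient_data")
  if (var(xa) == 0 && var(xb) == 0) {
    ## degenerate but well-defined limits: no spread at all
    same <- isTRUE(all.equal(mean(xa), mean(xb)))
    tt <- list(statistic = if (same) 0 else sign(mean(xa) - mean(xb)) * Inf,
               parameter = length(xa) + length(xb) - 2,
               p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(xa, xb, var.equal = equal_var,
                        alternative = "two.sided")
  }
  data.frame(metric = metric, group_a = group_a, group_b = group_b,
             n_a = length(xa), n_b = length(xb),
             mean_a = mean(xa), sd_a = sd(xa),
             mean_b = mean(xb), sd_b = sd(xb),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' One-way ANOVA across all groups
#'
#' Standard fixed-effects one-way ANOVA (equal-variance F test) of a
#' metric across every group present in the table.
#'
#' @inheritParams two_sample_test
#' @return Data frame row: `metric, k_groups, F, df1, df2, p`. When the
#'   within-group variance is exactly zero (all groups constant) the F
#'   statistic is undefined; `NA` is returned with a warning of class
#'   `vitmech_degenerate_anova`.
#' @export
one_way_anova <- function(table, metric, group_col = "group") {
  check_group_table(table, metric, group_col)
  g <- factor(table[[group_col]])
  y <- table[[metric]]
  if (nlevels(g) < 2L || any(tabulate(g) < 2L))
    vm_abort("need >= 2 groups with >= 2 values each",
             "vitmech_insufficient_data")
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (ss_within == 0) {
    vm_warn("zero within-group variance: F undefined",
            "vitmech_degenerate_anova")
    return(data.frame(metric = metric, k_groups = nlevels(g),
                      F = NA_real_, df1 = nlevels(g) - 1L,
                      df2 = length(y) - nlevels(g), p = NA_real_))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  data.frame(metric = metric, k_groups = nlevels(g),
             F = unname(ow$statistic),
             df1 = unname(ow$parameter[1L]), df2 = unname(ow$parameter[2L]),
             p = ow$p.value)
}

report_schema <- function() {
  data.frame(metric = character(), group = character(), n = integer(),
             mean = numeric(), sd = numeric())
}

#' Assemble a summary report from long-format metric tables
#'
#' Reads every `*.csv` under `results_dir` that has columns
#' `sample_id, group, metric, value` (other CSVs are ignored), and builds
#' a per-metric, per-group mean/SD/n summary plus all pairwise two-sample
#' tests per metric. Re-running on the same directory reproduces the same
#' report.
#'
#' @param results_dir Directory of long-format metric CSVs.
#' @param out_dir Optional: where to write `report_summary.csv` and
#'   `report_tests.csv`.
#' @param equal_var Passed to [two_sample_test()].
#' @return List with `summary` (metric x group rows), `tests` (pairwise
#'   comparisons; carries attribute `n_comparisons`), and `n_files`.
#' @export
build_report <- function(results_dir, out_dir = NULL, equal_var = FALSE) {
  files <- list.files(results_dir, pattern = "\\.csv$", full.names = TRUE,
                      recursive = TRUE)
  long <- list()
  for (f in files) {
    tab <- tryCatch(read.csv(f, stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (!is.null(tab) &&
        all(c("sample_id", "group", "metric", "value") %in% names(tab)))
      long[[length(long) + 1L]] <- tab[, c("sample_id", "group", "metric",
                                           "value")]
  }
  if (length(long) == 0L) {
    res <- list(summary = report_schema(),
                tests = data.frame(), n_files = 0L)
  } else {
    dat <- do.call(rbind, long)
    dat <- dat[complete.cases(dat), ]
    summ <- aggregate(value ~ metric + group, dat,
                      function(v) c(n = length(v), mean = mean(v),
                                    sd = sd(v)))
    summ <- data.frame(metric = summ$metric, group = summ$group,
                       n = as.integer(summ$value[, "n"]),
                       mean = summ$value[, "mean"], sd = summ$value[, "sd"])
    summ <- summ[order(summ$metric, summ$group), ]
    rownames(summ) <- NULL
    tests <- list()
    for (m in sort(unique(dat$metric))) {
      sub <- dat[dat$metric == m, ]
      gs <- sort(unique(sub$group))
      if (length(gs) < 2L) next
      for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
        if (sum(sub$group == gs[i]) < 2L || sum(sub$group == gs[j]) < 2L)
          next
        row <- tryCatch(
          two_sample_test(sub, "value", gs[i], gs[j], equal_var = equal_var),
          error = function(e) NULL)
        if (is.null(row)) next
        row$metric <- m
        tests[[length(tests) + 1L]] <- row
      }
    }
    tests <- if (length(tests) > 0L) do.call(rbind, tests) else data.frame()
    attr(tests, "n_comparisons") <- nrow(tests)
    res <- list(summary = summ, tests = tests, n_files = length(long))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$summary, file.path(out_dir, "report_summary.csv"),
              row.names = FALSE)
    write.csv(res$tests, file.path(out_dir, "report_tests.csv"),
              row.names = FALSE)
  }
  res
}
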