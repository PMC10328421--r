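# ---- test-result container -------------------------------------------------

pvs_test_result <- function(method, statistic, p_value, group_sizes = NULL,
                            notes = character()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), group_sizes = group_sizes,
                 notes = notes),
            class = "pvs_test_result")
}

#' @export
print.pvs_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %s, p = %s%s\n", x$method,
              format(signif(x$statistic, 4)), format_p(x$p_value),
              if (length(x$notes)) paste0(" [", paste(x$notes, collapse = "; "),
                                          "]") else ""))
  invisible(x)
}

#' Display formatting for p-values
#'
#' Two significant figures; values below 1e-4 print as `"<0.0001"`.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", format(signif(p, 2), scientific = FALSE,
                                     trim = TRUE))
}

median_iqr <- function(x) {
  # linear-interpolation quartiles (quantile type 7)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

# ---- descriptive summaries --------------------------------------------------

#' Cohort summary tables (medians/IQR and frequencies)
#'
#' Per-stratum medians with interquartile ranges for quantitative variables
#' and absolute plus relative (percentage) frequencies for categorical
#' ones, percentages computed on non-missing denominators (which are
#' printed). Percentages round half-up to one decimal. Empty strata are
#' emitted with n = 0 and a blank percentage.
#'
#' @param table cohort data.frame.
#' @param group_variable stratifying column (default `"group"`); `NULL`
#'   summarizes the whole table as one stratum.
#' @param quantitative,categorical character vectors of column names; the
#'   defaults cover the standard cohort dictionary, intersected with the
#'   columns present.
#' @return list with data.frames `quantitative` (variable, stratum, n,
#'   median, q1, q3) and `categorical` (variable, level, stratum, count,
#'   denominator, percent).
#' @export
summarize_cohort <- function(table, group_variable = "group",
                             quantitative = c("age_years",
                                              "pvs_volume_voxels",
                                              "max_slice_count"),
                             categorical = c("sex", "asd_type", "severity",
                                             "adhd", "epilepsy", "insomnia",
                                             "id_flag", "pvs_grade")) {
  if (nrow(table) == 0) stop("empty cohort table", call. = FALSE)
  if (!is.null(group_variable) && !group_variable %in% names(table))
    stop(sprintf("unknown stratum variable '%s'", group_variable),
         call. = FALSE)
  strata <- if (is.null(group_variable)) list(all = table)
            else split(table, table[[group_variable]], drop = FALSE)
  strata <- c(list(total = table), strata)
  quantitative <- intersect(quantitative, names(table))
  categorical <- intersect(categorical, names(table))

  qrows <- list()
  for (v in quantitative) for (s in names(strata)) {
    x <- strata[[s]][[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      qrows[[length(qrows) + 1L]] <- data.frame(
        variable = v, stratum = s, n = 0L,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    } else {
      m <- median_iqr(x)
      qrows[[length(qrows) + 1L]] <- data.frame(
        variable = v, stratum = s, n = length(x),
        median = m["median"], q1 = m["q1"], q3 = m["q3"])
    }
  }

  crows <- list()
  for (v in categorical) {
    levs <- sort(unique(table[[v]][!is.na(table[[v]])]))
    for (s in names(strata)) {
      x <- strata[[s]][[v]]
      denom <- sum(!is.na(x))
      for (lv in levs) {
        cnt <- sum(x == lv, na.rm = TRUE)
        crows[[length(crows) + 1L]] <- data.frame(
          variable = v, level = as.character(lv), stratum = s,
          count = cnt, denominator = denom,
          percent = if (denom > 0) round_half_up(100 * cnt / denom, 1)
                    else NA_real_)
      }
    }
  }
  list(quantitative = do.call(rbind, qrows),
       categorical = do.call(rbind, crows),
       row.names = NULL)
}

# ---- group comparisons ------------------------------------------------------

#' Compare a quantitative variable between groups
#'
#' Two groups: two-sided Mann-Whitney (exact when both groups have n <= 20
#' and there are no ties, otherwise the normal approximation with tie
#' correction). More than two groups: Kruskal-Wallis.
#'
#' @param table cohort data.frame.
#' @param variable quantitative column name.
#' @param group_variable grouping column name.
#' @return a `pvs_test_result`.
#' @export
compare_quantitative <- function(table, variable, group_variable) {
  for (v in c(variable, group_variable))
    if (!v %in% names(table)) stop(sprintf("unknown variable '%s'", v),
                                   call. = FALSE)
  ok <- !is.na(table[[variable]]) & !is.na(table[[group_variable]])
  groups <- split(table[[variable]][ok], table[[group_variable]][ok],
                  drop = FALSE)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0))
    stop(sprintf("empty group(s): %s",
                 paste(names(groups)[sizes == 0], collapse = ", ")),
         call. = FALSE)
  allv <- unlist(groups, use.names = FALSE)
  if (length(unique(allv)) == 1L) {
    method <- if (length(groups) == 2) "mann-whitney" else "kruskal-wallis"
    return(pvs_test_result(method, statistic = NA_real_, p_value = 1,
                           group_sizes = sizes,
                           notes = "all values tied across groups; p = 1"))
  }
  if (length(groups) == 2) {
    has_ties <- anyDuplicated(allv) > 0
    exact <- all(sizes <= 20) && !has_ties
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              exact = exact,
                                              correct = FALSE))
    pvs_test_result("mann-whitney", ht$statistic, ht$p.value, sizes,
                    notes = if (exact) "exact" else
                      "normal approximation with tie correction")
  } else {
    ht <- stats::kruskal.test(groups)
    pvs_test_result("kruskal-wallis", ht$statistic, ht$p.value, sizes)
  }
}

#' Compare a categorical variable between groups
#'
#' Builds the contingency table (row-wise deletion of missing values) and
#' applies the selection rule: Fisher's exact test when any expected cell
#' count is below 5, otherwise Pearson chi-square without continuity
#' correction. The rule outcome is recorded in the notes; `method` forces
#' either test.
#'
#' @param table cohort data.frame.
#' @param variable categorical column name.
#' @param group_variable grouping column name.
#' @param method `"auto"` (expected-count rule), `"chisq"` or `"fisher"`.
#' @return a `pvs_test_result`.
#' @export
compare_categorical <- function(table, variable, group_variable,
                                method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  for (v in c(variable, group_variable))
    if (!v %in% names(table)) stop(sprintf("unknown variable '%s'", v),
                                   call. = FALSE)
  ok <- !is.na(table[[variable]]) & !is.na(table[[group_variable]])
  tab <- base::table(table[[variable]][ok], table[[group_variable]][ok])
  compare_categorical_counts(tab, method)
}

#' Categorical comparison on a contingency table of counts
#'
#' The same selection rule as [compare_categorical()], operating directly
#' on a counts matrix (useful when only printed frequency tables are
#' available).
#'
#' @param x contingency matrix of counts (levels x groups).
#' @param method `"auto"`, `"chisq"` or `"fisher"`.
#' @return a `pvs_test_result`.
#' @export
compare_categorical_counts <- function(x,
                                       method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("degenerate contingency table (zero margin)", call. = FALSE)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  min_exp <- min(expected)
  use <- switch(method,
                auto = if (min_exp < 5) "fisher" else "chisq",
                method)
  note <- sprintf("min expected count %.2f; %s selected (%s)", min_exp, use,
                  if (method == "auto") "expected-count rule" else "forced")
  if (use == "chisq") {
    ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    pvs_test_result("chi-square", ht$statistic, ht$p.value,
                    group_sizes = colSums(x), notes = note)
  } else {
    ht <- stats::fisher.test(x, workspace = 2e7)
    pvs_test_result("fisher-exact",
                    statistic = if (!is.null(ht$estimate)) ht$estimate
                                else NA_real_,
                    ht$p.value, group_sizes = colSums(x), notes = note)
  }
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p-value (asymptotic t
#' approximation, which accommodates ties).
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs.
#' @return a `pvs_test_result` with the correlation as `statistic`.
#' @export
correlate_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input: ranks undefined", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  pvs_test_result("spearman", ht$estimate, ht$p.value,
                  group_sizes = length(x))
}

#' Shapiro-Wilk normality test
#'
#' Used to justify the nonparametric test choices in report narratives.
#'
#' @param x numeric, 3 <= n <= 5000 after missing-value removal.
#' @return a `pvs_test_result` with the W statistic.
#' @export
normality_shapiro <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("constant input: normality test undefined", call. = FALSE)
  ht <- stats::shapiro.test(x)
  pvs_test_result("shapiro-wilk", ht$statistic, ht$p.value,
                  group_sizes = length(x))
}

# ---- report builder ---------------------------------------------------------

report_row <- function(variable, comparison, res, alpha) {
  data.frame(variable = variable, comparison = comparison,
             method = res$method,
             statistic = if (is.null(res$statistic)) NA_real_
                         else as.numeric(res$statistic),
             p_value = res$p_value, p_formatted = format_p(res$p_value),
             significant = res$p_value < alpha,
             notes = paste(res$notes, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Build the cohort comparison report
#'
#' Runs the standard case-control comparison set on a cohort table:
#' quantitative variables by group (Mann-Whitney / Kruskal-Wallis),
#' categorical variables by group (chi-square / Fisher by the
#' expected-count rule), WM-PVS volume by sex, and volume by ASD severity
#' when present. Rows are flagged significant at `alpha` (default 0.05).
#'
#' @param table cohort data.frame (see [generate_cohort()] for the column
#'   dictionary; `group` and `sex` are required).
#' @param alpha significance level.
#' @param categorical_test `"auto"`, `"chisq"` or `"fisher"` passed through
#'   to the categorical comparisons.
#' @return An object of class `pvs_report`: list with `summary` (from
#'   [summarize_cohort()]), `comparisons` (data.frame), `alpha`.
#' @export
build_report <- function(table, alpha = 0.05,
                         categorical_test = c("auto", "chisq", "fisher")) {
  categorical_test <- match.arg(categorical_test)
  stopifnot(all(c("group", "sex") %in% names(table)))
  rows <- list()
  add <- function(variable, comparison, res)
    rows[[length(rows) + 1L]] <<- report_row(variable, comparison, res, alpha)

  quant <- intersect(c("age_years", "pvs_volume_voxels", "max_slice_count"),
                     names(table))
  for (v in quant)
    add(v, "by group", compare_quantitative(table, v, "group"))
  cats <- intersect(c("sex", "adhd", "epilepsy", "insomnia", "id_flag",
                      "pvs_grade"), names(table))
  for (v in cats)
    add(v, "by group", compare_categorical(table, v, "group",
                                           method = categorical_test))
  if ("pvs_volume_voxels" %in% names(table)) {
    add("pvs_volume_voxels", "by sex",
        compare_quantitative(table, "pvs_volume_voxels", "sex"))
    if ("pvs_grade" %in% names(table) &&
        length(unique(stats::na.omit(table$pvs_grade))) > 1 &&
        length(unique(stats::na.omit(table$pvs_volume_voxels))) > 1) {
      add("pvs_volume_voxels vs pvs_grade", "correlation",
          correlate_spearman(table$pvs_volume_voxels, table$pvs_grade))
    }
    if ("severity" %in% names(table) &&
        length(unique(stats::na.omit(table$severity))) >= 2) {
      asd <- table[!is.na(table$severity), ]
      add("pvs_volume_voxels", "by severity",
          compare_quantitative(asd, "pvs_volume_voxels", "severity"))
    }
  }
  structure(list(summary = summarize_cohort(table),
                 comparisons = do.call(rbind, rows), alpha = alpha),
            class = "pvs_report")
}

#' @export
print.pvs_report <- function(x, ...) {
  cat(sprintf("<pvs_report> %d comparisons, %d significant at alpha = %g\n",
              nrow(x$comparisons), sum(x$comparisons$significant), x$alpha))
  print(x$comparisons[, c("variable", "comparison", "method", "p_formatted",
                          "significant")], row.names = FALSE)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `report.csv` (comparison rows), `summary_quantitative.csv`,
#' `summary_categorical.csv` and a machine-readable `report.json`.
#'
#' @param report a `pvs_report`.
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$comparisons, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary$quantitative,
                   file.path(dir, "summary_quantitative.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary$categorical,
                   file.path(dir, "summary_categorical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(alpha = report$alpha,
                            comparisons = report$comparisons,
                            summary = report$summary),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
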