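# Nonparametric cohort statistics: summaries, group comparisons, test
# selection rule, correlation, normality, report assembly.

toy_cohort <- function() {
  data.frame(id = sprintf("S%02d", 1:12),
             group = rep(c("ASD", "NP-non-ASD"), each = 6),
             sex = rep(c("M", "F"), 6),
             age_years = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 7),
             pvs_volume_voxels = c(500, 700, 300, 900, 650, 420,
                                   400, 350, 500, 320, 610, 380),
             pvs_grade = c(3, 4, 2, 4, 3, 2, 2, 2, 3, 2, 3, 2),
             stringsAsFactors = FALSE)
}

test_that("median/IQR follow the linear-interpolation quartile convention", {
  tab <- data.frame(group = rep("A", 5), sex = "M", x = 1:5)
  s <- summarize_cohort(tab, group_variable = "group", quantitative = "x",
                        categorical = character())
  row <- s$quantitative[s$quantitative$stratum == "A", ]
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
})

test_that("percentages round half-up on non-missing denominators", {
  tab <- data.frame(group = "ASD", sex = "M",
                    severity = rep(1:3, c(10, 18, 36)))
  s <- summarize_cohort(tab, group_variable = "group",
                        quantitative = character(), categorical = "severity")
  sev <- s$categorical[s$categorical$stratum == "ASD", ]
  expect_equal(sev$percent[match(1:3, sev$level)], c(15.6, 28.1, 56.3))
  expect_equal(unique(sev$denominator), 64)
  # 56.25 must round UP to 56.3, not to even
  expect_equal(round_half_up(56.25, 1), 56.3)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("empty strata are emitted with n = 0 and blank percentage", {
  tab <- data.frame(group = factor(c("A", "A"), levels = c("A", "B")),
                    sex = "M", x = c(1, 2), f = c("y", "n"))
  s <- summarize_cohort(tab, group_variable = "group", quantitative = "x",
                        categorical = "f")
  empty_q <- s$quantitative[s$quantitative$stratum == "B", ]
  expect_equal(empty_q$n, 0L)
  expect_true(is.na(empty_q$median))
  empty_c <- s$categorical[s$categorical$stratum == "B", ]
  expect_true(all(empty_c$count == 0))
  expect_true(all(is.na(empty_c$percent)))
  expect_error(summarize_cohort(tab, group_variable = "nope"), "unknown stratum")
})

test_that("quantitative comparisons: ties, separation, >2 groups", {
  tab <- data.frame(g = rep(c("a", "b"), each = 4), x = rep(c(1, 2, 3, 4), 2))
  res <- compare_quantitative(tab, "x", "g")
  expect_equal(res$method, "mann-whitney")
  expect_equal(res$p_value, 1)

  sep <- data.frame(g = rep(c("a", "b"), each = 30), x = c(1:30, 101:130))
  res2 <- compare_quantitative(sep, "x", "g")
  expect_lt(res2$p_value, 0.001)

  tri <- data.frame(g = rep(c("a", "b", "c"), each = 10), x = rnorm(30))
  expect_equal(compare_quantitative(tri, "x", "g")$method, "kruskal-wallis")

  allsame <- data.frame(g = rep(c("a", "b"), each = 3), x = 5)
  res3 <- compare_quantitative(allsame, "x", "g")
  expect_equal(res3$p_value, 1)
  expect_match(res3$notes, "tied")

  none <- data.frame(g = factor(rep("a", 3), levels = c("a", "b")), x = 1:3)
  expect_error(compare_quantitative(none, "x", "g"), "empty group|2 groups")
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(31)
  rej <- 0
  for (i in 1:500) {
    tab <- data.frame(g = rep(c("a", "b", "c"), each = 30), x = rnorm(90))
    rej <- rej + (compare_quantitative(tab, "x", "g")$p_value < 0.05)
  }
  expect_gt(rej / 500, 0.03)
  expect_lt(rej / 500, 0.07)
})

test_that("categorical rule: chi-square when expected counts allow, Fisher below 5", {
  # printed 2x2 tables: epilepsy 8/72 vs 9/64, gliosis 14/72 vs 13/64
  epi <- matrix(c(8, 64, 9, 55), 2, 2)
  res <- compare_categorical_counts(epi)
  expect_equal(res$method, "chi-square")
  expect_equal(round(res$p_value, 2), 0.60)
  gli <- matrix(c(14, 58, 13, 51), 2, 2)
  expect_equal(round(compare_categorical_counts(gli)$p_value, 2), 0.90)

  # expected counts exactly 5 stay with chi-square (rule is strictly < 5)
  expect_equal(compare_categorical_counts(matrix(c(1, 9, 9, 1), 2, 2))$method,
               "chi-square")
  small <- matrix(c(1, 8, 9, 1), 2, 2)  # min expected 10*9/19 < 5
  res2 <- compare_categorical_counts(small)
  expect_equal(res2$method, "fisher-exact")
  expect_equal(res2$p_value, oracle_fisher_2x2(1, 9, 8, 1), tolerance = 1e-9)
  # the Fisher p of the spec example table matches brute-force enumeration
  forced <- compare_categorical_counts(matrix(c(1, 9, 9, 1), 2, 2),
                                       method = "fisher")
  expect_equal(forced$p_value, oracle_fisher_2x2(1, 9, 9, 1), tolerance = 1e-9)
  expect_match(forced$notes, "forced")

  expect_error(compare_categorical_counts(matrix(c(0, 0, 3, 4), 2, 2)),
               "degenerate")
})

test_that("Fisher matches hypergeometric enumeration on all margins <= 8", {
  # exhaustive check on a sub-grid here; the full <=15 sweep runs in the
  # acceptance suite
  for (r1 in 1:8) for (r2 in 1:8) for (a in 0:r1) for (c in 0:r2) {
    b <- r1 - a; d <- r2 - c
    if (a + c == 0 || b + d == 0) next
    m <- matrix(c(a, b, c, d), 2, 2)
    p_pkg <- stats::fisher.test(m)$p.value
    expect_equal(p_pkg, oracle_fisher_2x2(a, b, c, d), tolerance = 1e-7)
  }
})

test_that("categorical comparison builds its table from the cohort columns", {
  tab <- toy_cohort()
  tab$flag <- rep(c(TRUE, FALSE), 6)
  res <- compare_categorical(tab, "flag", "group")
  expect_true(res$method %in% c("chi-square", "fisher-exact"))
  expect_equal(sum(res$group_sizes), 12)
})

test_that("Spearman: monotone extremes, brute-force formula, constants", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(correlate_spearman(x, 2 * x + 1)$statistic, 1)
  expect_equal(correlate_spearman(x, -x)$statistic, -1)
  set.seed(11)
  for (rep in 1:10) {
    a <- sample(100, 8); b <- sample(100, 8)
    expect_equal(correlate_spearman(a, b)$statistic,
                 oracle_spearman_rho(a, b), tolerance = 1e-12)
  }
  expect_error(correlate_spearman(rep(1, 5), 1:5), "constant")
  expect_error(correlate_spearman(1:2, 2:1), "3 complete pairs")
})

test_that("Shapiro-Wilk calibration and power", {
  set.seed(17)
  rej <- 0
  for (i in 1:300) rej <- rej + (normality_shapiro(rnorm(100))$p_value < 0.05)
  expect_gt(rej / 300, 0.02)
  expect_lt(rej / 300, 0.09)
  power <- 0
  for (i in 1:100) power <- power + (normality_shapiro(rlnorm(100, sd = 1))$p_value < 0.01)
  expect_gte(power / 100, 0.95)
  expect_error(normality_shapiro(rep(2, 10)), "constant")
  expect_error(normality_shapiro(c(1, 2)), "3 <= n")
})

test_that("p-value formatting follows the display convention", {
  expect_equal(format_p(0.6034), "0.6")
  expect_equal(format_p(0.0432), "0.043")
  expect_equal(format_p(9e-5), "<0.0001")
  expect_equal(format_p(0.000101), "0.0001")  # two significant figures
})

test_that("report builder flags effects and is deterministic", {
  p <- cohort_sim_params(n_asd = 150, n_control = 150, effect_male = 1.5,
                         seed = 5)
  tab <- generate_cohort(p)
  rep1 <- build_report(tab)
  rep2 <- build_report(tab)
  expect_identical(rep1$comparisons, rep2$comparisons)
  male_row <- rep1$comparisons[rep1$comparisons$variable == "pvs_volume_voxels" &
                                 rep1$comparisons$comparison == "by sex", ]
  expect_true(male_row$significant)
  # every percentage printed equals count/denominator after rounding
  cc <- rep1$summary$categorical
  ok <- cc$denominator > 0
  expect_equal(cc$percent[ok], round_half_up(100 * cc$count[ok] / cc$denominator[ok], 1))
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c("report.csv", "report.json",
                                               "summary_categorical.csv")))))
})

test_that("null cohorts flag about 5% of comparison rows", {
  flagged <- 0; total <- 0
  for (i in 1:60) {
    p <- cohort_sim_params(n_asd = 40, n_control = 40, effect_male = 1,
                           effect_young_asd = 1, effect_severity_per_level = 1,
                           effect_insomnia = 1,
                           comorbidity_rates = list(
                             adhd = c(asd = 0.2, control = 0.2),
                             epilepsy = c(asd = 0.15, control = 0.15),
                             insomnia = c(asd = 0.3, control = 0.3),
                             id = c(asd = 0.3, control = 0.3)),
                           seed = 4000 + i)
    tab <- generate_cohort(p)
    cmp <- build_report(tab)$comparisons
    # group comparisons only: volume/grade/count depend on covariate nulls
    rows <- cmp[cmp$comparison == "by group" &
                  cmp$variable %in% c("age_years", "sex", "adhd", "epilepsy",
                                      "insomnia", "id_flag"), ]
    flagged <- flagged + sum(rows$significant)
    total <- total + nrow(rows)
  }
  expect_gt(flagged / total, 0.01)
  expect_lt(flagged / total, 0.10)
})
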