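make_table <- function() {
  records <- tibble::tibble(
    subject_id = c("C001", "C001", "C001", "C002", "M001", "M001"),
    segment_id = sprintf("s%d", 1:6),
    diameter_um = c(10, 20, 30, 14, 18, 25),
    va_mm_s = c(0.5, 0.6, 0.7, 0.4, 0.3, 0.5),
    vs_mm_s = cross_sectional_velocity(c(0.5, 0.6, 0.7, 0.4, 0.3, 0.5),
                                       c(10, 20, 30, 14, 18, 25))
  )
  records$q_pl_s <- volume_flow(records$vs_mm_s, records$diameter_um)
  records$wsr_per_s <- wall_shear_rate(records$vs_mm_s, records$diameter_um)
  records$group <- assign_group(records$diameter_um)
  subjects <- tibble::tibble(subject_id = c("C001", "C002", "M001", "M002"),
                             cohort = c("control", "control", "mi", "mi"))
  cohort_table(records, subjects)
}

test_that("cohort table validates subjects and labels", {
  tab <- make_table()
  expect_s3_class(tab, "cohort_table")
  rec <- tibble::tibble(subject_id = "X9", diameter_um = 10)
  subj <- tibble::tibble(subject_id = "C001", cohort = "control")
  expect_error(cohort_table(rec, subj), "unknown subjects")
  subj2 <- tibble::tibble(subject_id = "X9", cohort = "patient")
  expect_error(cohort_table(rec, subj2), "cohort labels")
})

test_that("per-patient aggregation averages all of a subject's segments", {
  tab <- make_table()
  agg <- suppressWarnings(aggregate_per_patient(tab, "D"))
  expect_equal(agg$value[agg$subject_id == "C001"], 20)  # mean(10, 20, 30)
  expect_equal(agg$subject_id, sort(agg$subject_id))
  expect_warning(aggregate_per_patient(tab, "D"), "no records")
  expect_error(aggregate_per_patient(tab, "bogus"), "unknown parameter")
})

test_that("per-group aggregation is segment-level and group-filtered", {
  tab <- make_table()
  g1 <- aggregate_per_group(tab, "D", 1)
  expect_equal(nrow(g1), 1)   # only the 10 um segment
  expect_warning(empty <- aggregate_per_group(dplyr::filter(tab, group != 2),
                                              "Va", 2), "no records")
  expect_equal(nrow(empty), 0)
})

test_that("patient-level and segment-pooled means differ on unbalanced data", {
  tab <- make_table()
  patient_mean <- mean(suppressWarnings(
    aggregate_per_patient(tab, "D"))$value[1:2])   # control subjects
  pooled_mean <- mean(tab$diameter_um[tab$cohort == "control"])
  expect_false(isTRUE(all.equal(patient_mean, pooled_mean)))
})

test_that("identical arms compare with p = 1", {
  set.seed(51)
  x <- rnorm(30)
  cmp <- compare_two_cohorts(x, x)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$test, "t-test")
})

test_that("a shift of the study's size is detected at large n", {
  set.seed(52)
  control <- rnorm(1000, 0.53, 0.15)
  mi <- rnorm(1000, 0.49, 0.17)
  cmp <- compare_two_cohorts(control, mi, parameter = "Va")
  expect_equal(cmp$test, "t-test")
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$summary$mean[1], cmp$summary$mean[2])
})

test_that("skewed arms are gated to the Mann-Whitney test", {
  set.seed(53)
  control <- rlnorm(1000, 0, 1)
  mi <- rlnorm(1000, 0.1, 1)
  cmp <- compare_two_cohorts(control, mi)
  expect_equal(cmp$test, "mann-whitney")
})

test_that("comparison is symmetric and small arms are rejected", {
  set.seed(54)
  a <- rnorm(40, 1); b <- rnorm(40, 1.3)
  c1 <- compare_two_cohorts(a, b)
  c2 <- compare_two_cohorts(b, a)
  expect_equal(c1$p_value, c2$p_value)
  expect_error(compare_two_cohorts(c(1, 2), rnorm(10)), "insufficient")
})

test_that("tidiers return one row per arm and one row per test", {
  set.seed(55)
  cmp <- compare_two_cohorts(rnorm(20), rnorm(20), parameter = "Q")
  td <- tidy(cmp)
  expect_equal(nrow(td), 2)
  expect_true(all(c("parameter", "cohort", "mean", "sd") %in% names(td)))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$parameter, "Q")
})

test_that("categorical gate follows the expected-count rule", {
  even <- compare_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$test, "chi-square")
  expect_equal(even$p_value, 1)
  fisher <- compare_categorical(matrix(c(0, 12, 56, 47), 2))
  expect_equal(fisher$test, "fisher")
  chisq <- compare_categorical(matrix(c(38, 47, 18, 12), 2))
  expect_equal(chisq$test, "chi-square")
  expect_error(compare_categorical(matrix(0, 2, 2)), "all-zero")
})

test_that("identical groups give a null ANOVA", {
  set.seed(56)
  g <- rnorm(20)
  an <- anova_posthoc(list(a = g, b = g, c = g))
  expect_lt(an$f_statistic, 1e-20)
  expect_equal(an$p_value, 1)
})

test_that("only pairs with the shifted group reach significance", {
  set.seed(57)
  an <- anova_posthoc(list(a = rnorm(50), b = rnorm(50), c = rnorm(50, 2)))
  pw <- an$pairwise
  with_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adj[with_c] < 0.05))
  expect_true(all(pw$p_adj[!with_c] > 0.05))
  expect_lt(an$p_value, 0.001)
})

test_that("unequal variances gate the post-hoc to Games-Howell", {
  set.seed(58)
  an <- anova_posthoc(list(a = rnorm(40, 0, 1), b = rnorm(40, 0, 1),
                           c = rnorm(40, 0.5, sqrt(10))))
  expect_equal(an$posthoc_method, "games-howell")
  an2 <- anova_posthoc(list(a = rnorm(40), b = rnorm(40), c = rnorm(40)))
  expect_equal(an2$posthoc_method, "bonferroni")
  expect_error(anova_posthoc(list(rnorm(5), rnorm(5))), "3 groups")
})

test_that("repeatability summarises paired differences", {
  r0 <- repeatability(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$cr, 0)
  expect_error(repeatability(1, 2), "2 pairs")
  m2 <- rnorm(38)
  d <- diffs_with_sd(38, 2.14, 0.03)
  r <- repeatability(m2 + d, m2, parameter = "Q")
  expect_equal(r$sd_diff, 2.14, tolerance = 1e-12)
  expect_equal(round(r$cr, 2), 4.19)
  # swapping the measurement columns flips the sign but not the CR
  r_sw <- repeatability(m2, m2 + d)
  expect_equal(r_sw$cr, r$cr)
  expect_equal(r_sw$mean_diff, -r$mean_diff)
})

test_that("null rejection rate of the gated comparison is near alpha", {
  # compact 400-rep check; the acceptance suite runs 2000 reps
  set.seed(59)
  rej <- mean(vapply(1:400, function(i) {
    compare_two_cohorts(rnorm(50), rnorm(50))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
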