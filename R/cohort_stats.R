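param_column <- function(parameter) {
  cols <- c(D = "diameter_um", Va = "va_mm_s", Q = "q_pl_s", WSR = "wsr_per_s")
  if (!parameter %in% names(cols)) {
    stop("unknown parameter '", parameter, "'; expected one of ",
         paste(names(cols), collapse = ", "))
  }
  unname(cols[parameter])
}

#' Join segment records with subject metadata into a cohort table
#'
#' @param records Segment-record tibble ([build_segment_records()]).
#' @param subjects Tibble with `subject_id`, `cohort` (levels `"control"`,
#'   `"mi"`) and optional covariates.
#' @return Tibble of class `cohort_table`: records joined with cohort
#'   labels.
#' @export
cohort_table <- function(records, subjects) {
  stopifnot(is.data.frame(records), is.data.frame(subjects))
  stopifnot(all(c("subject_id", "cohort") %in% names(subjects)))
  bad <- setdiff(unique(records$subject_id), subjects$subject_id)
  if (length(bad)) stop("records reference unknown subjects: ",
                        paste(bad, collapse = ", "))
  lv <- setdiff(unique(subjects$cohort), c("control", "mi"))
  if (length(lv)) stop("unknown cohort labels: ", paste(lv, collapse = ", "))
  out <- dplyr::left_join(records, subjects, by = "subject_id")
  class(out) <- c("cohort_table", class(out))
  attr(out, "subjects") <- subjects
  out
}

#' Per-patient parameter averages
#'
#' Overall (all-vessel) comparisons operate on one value per patient: the
#' mean of the parameter over all of that patient's vessel segments, all
#' views pooled. Subjects contributing no records are omitted with a
#' warning.
#'
#' @param table A [cohort_table()] (or any records tibble with `subject_id`
#'   and `cohort`).
#' @param parameter One of `"D"`, `"Va"`, `"Q"`, `"WSR"`.
#' @return Tibble `subject_id`, `cohort`, `value`, ordered by `subject_id`.
#' @export
aggregate_per_patient <- function(table, parameter) {
  col <- param_column(parameter)
  stopifnot(nrow(table) > 0)
  subjects <- attr(table, "subjects")
  if (!is.null(subjects)) {
    silent <- setdiff(subjects$subject_id, table$subject_id)
    if (length(silent)) {
      warning(length(silent), " subject(s) contributed no records and are omitted: ",
              paste(silent, collapse = ", "))
    }
  }
  out <- table |>
    dplyr::group_by(.data$subject_id, .data$cohort) |>
    dplyr::summarise(value = mean(.data[[col]]), .groups = "drop") |>
    dplyr::arrange(.data$subject_id)
  out
}

#' Segment-level values within one diameter group
#'
#' Group-stratified comparisons use every vessel segment falling in the
#' group, not per-patient averages: the two aggregation rules are distinct
#' and deliberately kept separate.
#'
#' @inheritParams aggregate_per_patient
#' @param vessel_group Integer 1-4.
#' @return Tibble `cohort`, `subject_id`, `value` at segment level.
#' @export
aggregate_per_group <- function(table, parameter, vessel_group) {
  col <- param_column(parameter)
  stopifnot(vessel_group %in% 1:4)
  out <- table |>
    dplyr::filter(.data$group == vessel_group) |>
    dplyr::transmute(cohort = .data$cohort, subject_id = .data$subject_id,
                     value = .data[[col]])
  if (nrow(out) == 0) warning("no records in vessel group ", vessel_group)
  out
}

normality_p <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  if (stats::sd(x) == 0) return(0)  # degenerate: treat as non-normal
  if (method == "lilliefors") {
    return(suppressWarnings(nortest::lillie.test(x)$p.value))
  }
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

ci_mean <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0) return(c(mean(x), mean(x)))
  se <- stats::sd(x) / sqrt(n)
  mean(x) + c(-1, 1) * stats::qt(1 - (1 - level) / 2, n - 1) * se
}

#' Compare a parameter between two cohorts with normality gating
#'
#' Normality of each arm is assessed by a Kolmogorov-Smirnov test against a
#' normal distribution with sample-estimated parameters (a Lilliefors
#' variant is available). If both arms pass at `alpha`, the arms are
#' compared with the independent-samples t-test; otherwise with the
#' Mann-Whitney U test.
#'
#' @param control,mi Numeric vectors (at least 3 values each).
#' @param alpha Significance level for the normality gate.
#' @param parameter Label carried into the result.
#' @param normality `"ks"` (plain KS with estimated parameters) or
#'   `"lilliefors"`.
#' @return Object of class `cohort_comparison` with per-arm summaries, the
#'   test used and its p-value. See [tidy.cohort_comparison()].
#' @export
compare_two_cohorts <- function(control, mi, alpha = 0.05,
                                parameter = "parameter",
                                normality = c("ks", "lilliefors")) {
  normality <- match.arg(normality)
  if (length(control) < 3 || length(mi) < 3) {
    stop("insufficient data: each arm needs at least 3 values")
  }
  p_norm <- c(control = normality_p(control, normality),
              mi = normality_p(mi, normality))
  both_normal <- all(p_norm > alpha)
  if (stats::sd(control) == 0 && stats::sd(mi) == 0 &&
      mean(control) == mean(mi)) {
    test <- "t-test"; p <- 1
  } else if (both_normal) {
    test <- "t-test"
    p <- stats::t.test(control, mi)$p.value
  } else {
    test <- "mann-whitney"
    p <- suppressWarnings(stats::wilcox.test(control, mi)$p.value)
  }
  structure(
    list(parameter = parameter, test = test, p_value = p,
         alpha = alpha, normality_p = p_norm, both_normal = both_normal,
         summary = tibble::tibble(
           cohort = c("control", "mi"),
           n = c(length(control), length(mi)),
           mean = c(mean(control), mean(mi)),
           sd = c(stats::sd(control), stats::sd(mi)),
           median = c(stats::median(control), stats::median(mi)),
           ci_low = c(ci_mean(control)[1], ci_mean(mi)[1]),
           ci_high = c(ci_mean(control)[2], ci_mean(mi)[2])
         )),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s: %s, p = %.4g\n",
              x$parameter, x$test, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @rdname compare_two_cohorts
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  dplyr::mutate(x$summary, parameter = x$parameter, .before = 1)
}

#' @rdname compare_two_cohorts
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, test = x$test, p_value = x$p_value,
                 normal_control = x$normality_p[["control"]] > x$alpha,
                 normal_mi = x$normality_p[["mi"]] > x$alpha)
}

#' Compare a categorical 2x2 table between cohorts
#'
#' Pearson chi-square when all expected cell counts reach 5 and no observed
#' cell is empty, Fisher's exact test otherwise.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return Object of class `cohort_comparison` (categorical flavour) with
#'   fields `test`, `p_value`, `proportions`.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5) || any(counts == 0)) {
    test <- "fisher"
    p <- stats::fisher.test(counts)$p.value
  } else {
    test <- "chi-square"
    p <- stats::chisq.test(counts, correct = FALSE)$p.value
  }
  structure(
    list(parameter = "categorical", test = test, p_value = p,
         counts = counts, proportions = prop.table(counts, margin = 2)),
    class = c("categorical_comparison", "cohort_comparison")
  )
}

# Games-Howell pairwise comparisons: Welch statistic referred to the
# studentized range distribution; no pooled variance assumption.
games_howell <- function(values, labels) {
  gs <- split(values, labels)
  k <- length(gs)
  nm <- names(gs)
  n <- vapply(gs, length, numeric(1))
  m <- vapply(gs, mean, numeric(1))
  v <- vapply(gs, stats::var, numeric(1))
  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    t <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(t * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      group1 = nm[i], group2 = nm[j], estimate = m[i] - m[j], p_adj = p)
  }
  dplyr::bind_rows(rows)
}

#' One-way ANOVA with variance-gated post-hoc tests
#'
#' One-way ANOVA across three or more groups, followed by pairwise
#' post-hoc comparisons: Bonferroni-adjusted pairwise t-tests when Levene's
#' test (centred on the mean) does not reject homogeneity of variance at
#' `alpha`, Games-Howell otherwise.
#'
#' @param groups Named (or unnamed) list of numeric vectors, each with at
#'   least 3 values.
#' @param alpha Significance level used by the homogeneity gate.
#' @return Object of class `anova_posthoc` with `f_statistic`, `p_value`,
#'   `levene_p`, `posthoc_method`, `pairwise` tibble.
#' @export
anova_posthoc <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) stop("ANOVA needs at least 3 groups")
  if (any(vapply(groups, length, numeric(1)) < 3)) {
    stop("each group needs at least 3 values")
  }
  if (is.null(names(groups))) {
    names(groups) <- sprintf("g%d", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, numeric(1))),
                   levels = names(groups))
  fit <- stats::aov(values ~ labels)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  lev <- car::leveneTest(values ~ labels, center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  if (levene_p > alpha) {
    method <- "bonferroni"
    pw <- stats::pairwise.t.test(values, labels, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    pm <- pw$p.value
    rows <- list()
    for (i in rownames(pm)) for (j in colnames(pm)) {
      if (!is.na(pm[i, j])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group1 = j, group2 = i,
          estimate = mean(groups[[j]]) - mean(groups[[i]]),
          p_adj = min(1, pm[i, j]))
      }
    }
    pairwise <- dplyr::bind_rows(rows)
  } else {
    method <- "games-howell"
    pairwise <- games_howell(values, labels)
  }
  structure(
    list(f_statistic = f, p_value = p, levene_p = levene_p,
         posthoc_method = method, pairwise = pairwise,
         group_means = vapply(groups, mean, numeric(1))),
    class = "anova_posthoc"
  )
}

#' @export
print.anova_posthoc <- function(x, ...) {
  cat(sprintf("<anova_posthoc> F = %.4g, p = %.4g; post-hoc: %s (Levene p = %.3g)\n",
              x$f_statistic, x$p_value, x$posthoc_method, x$levene_p))
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_posthoc
#' @param x An `anova_posthoc` object.
#' @param ... Unused.
#' @export
tidy.anova_posthoc <- function(x, ...) x$pairwise

#' @rdname anova_posthoc
#' @export
glance.anova_posthoc <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 levene_p = x$levene_p, posthoc_method = x$posthoc_method)
}

#' Test-retest repeatability of paired measurements
#'
#' For paired repeat measurements the coefficient of repeatability is 1.96
#' times the sample standard deviation of the paired differences: 95% of
#' repeat differences are expected within it. The interval reported is the
#' mean difference plus/minus the coefficient.
#'
#' @param m1,m2 Numeric vectors of first and second measurements (same
#'   length, at least 2 pairs); alternatively `m1` may be a two-column data
#'   frame or matrix.
#' @param parameter Label carried into the result.
#' @return Object of class `repeatability_result` with `mean_diff`,
#'   `sd_diff`, `cr`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
repeatability <- function(m1, m2 = NULL, parameter = "parameter") {
  if (is.null(m2)) {
    stopifnot(ncol(m1) == 2)
    m2 <- m1[[2]]; m1 <- m1[[1]]
  }
  stopifnot(length(m1) == length(m2))
  if (length(m1) < 2) stop("repeatability needs at least 2 pairs")
  d <- m1 - m2
  sd_diff <- stats::sd(d)
  cr <- 1.96 * sd_diff
  structure(
    list(parameter = parameter, mean_diff = mean(d), sd_diff = sd_diff,
         cr = cr, ci_low = mean(d) - cr, ci_high = mean(d) + cr,
         n_pairs = length(d)),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "<repeatability> %s: mean diff %.4g +/- %.4g (SD), CR %.4g (95%% CI %.4g to %.4g), n = %d\n",
    x$parameter, x$mean_diff, x$sd_diff, x$cr, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

#' @rdname repeatability
#' @param x A `repeatability_result`.
#' @param ... Unused.
#' @export
tidy.repeatability_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, mean_diff = x$mean_diff,
                 sd_diff = x$sd_diff, cr = x$cr, ci_low = x$ci_low,
                 ci_high = x$ci_high, n_pairs = x$n_pairs)
}
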