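#' Classify cases as molecularly monotypic or polytypic
#'
#' A case is polytypic when its analysed regions carry at least two distinct
#' molecular subtype calls, and monotypic otherwise. Classification is
#' invariant to region order and to duplicated identical calls.
#'
#' @param metadata Per-core metadata tibble with `case_id` and `subtype`
#'   (and optionally case-level `ihc_class`, `grade` columns used by
#'   [cohort_summary()]).
#' @return Tibble with one row per case: `case_id`, `n_regions`,
#'   `n_subtypes`, `subtypes` (collapsed label string), `typy`
#'   (`"monotypic"`/`"polytypic"`).
#' @examples
#' classify_typy(example_cohort_metadata())
#' @export
classify_typy <- function(metadata) {
  stopifnot(all(c("case_id", "subtype") %in% names(metadata)))
  bad <- is.na(metadata$subtype)
  if (any(bad)) {
    abort("Every analysed core needs a subtype call",
      class = "mxifhet_validation_error"
    )
  }
  metadata |>
    group_by(.data$case_id) |>
    summarise(
      n_regions = dplyr::n(),
      n_subtypes = dplyr::n_distinct(.data$subtype),
      subtypes = paste(sort(unique(.data$subtype)), collapse = "+"),
      .groups = "drop"
    ) |>
    mutate(typy = ifelse(.data$n_subtypes >= 2, "polytypic", "monotypic"))
}

#' Cohort composition summary
#'
#' Case-level counts and percentages: polytypic fraction, and (when the
#' metadata carries them) clinical IHC class and grade categories. One row
#' per (metric, category) pair.
#'
#' @param metadata Per-core metadata tibble; see [classify_typy()].
#' @return Tibble `metric`, `category`, `n`, `pct` (percent of cases).
#' @examples
#' cohort_summary(example_cohort_metadata())
#' @export
cohort_summary <- function(metadata) {
  typy <- classify_typy(metadata)
  n_cases <- nrow(typy)
  rows <- typy |>
    count(.data$typy, name = "n") |>
    mutate(metric = "typy") |>
    rename(category = "typy")
  case_level <- metadata |>
    distinct(.data$case_id, dplyr::across(dplyr::any_of(c("ihc_class", "grade"))))
  for (colnm in intersect(c("ihc_class", "grade"), names(case_level))) {
    rows <- bind_rows(
      rows,
      case_level |>
        count(.data[[colnm]], name = "n") |>
        mutate(metric = colnm) |>
        rename(category = dplyr::all_of(colnm))
    )
  }
  rows |>
    mutate(pct = 100 * .data$n / n_cases) |>
    relocate("metric", "category", "n", "pct")
}

#' Compare a per-core measurement across groups
#'
#' One-way fixed-effects ANOVA (two or more groups) or the two-sample
#' Wilcoxon rank-sum test (exactly two groups). Cores are treated as
#' independent observations; no multiple-testing correction is applied by
#' default (set `p_adjust` when comparing many features and adjust the
#' resulting column yourself, or use [stats::p.adjust] downstream). The
#' Wilcoxon test is exact when the combined sample size is at most 20 and
#' the data are tie-free, and uses the normal approximation with continuity
#' correction otherwise.
#'
#' @param data Data frame of per-core values.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column.
#' @param test `"anova"` or `"wilcoxon"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `df1`, `df2`
#'   (ANOVA only), `n`.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
#' compare_groups(d, "v", "g", test = "anova")
#' @export
compare_groups <- function(data, value, group, test = c("anova", "wilcoxon")) {
  test <- match.arg(test)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (length(v) < 2) {
    abort("At least 2 values are required", class = "mxifhet_validation_error")
  }
  sizes <- table(g)
  if (any(sizes == 0) || length(sizes) < 2) {
    abort("Every group needs at least one value and >= 2 groups are required",
      class = "mxifhet_validation_error"
    )
  }
  if (test == "anova") {
    fit <- aov(v ~ g)
    s <- summary(fit)[[1]]
    tibble(
      test = "anova",
      statistic = s[["F value"]][1],
      p_value = s[["Pr(>F)"]][1],
      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
      n = length(v)
    )
  } else {
    if (length(sizes) != 2) {
      abort("Wilcoxon rank-sum requires exactly 2 groups",
        class = "mxifhet_validation_error"
      )
    }
    x <- v[g == levels(g)[1]]
    y <- v[g == levels(g)[2]]
    exact <- (length(v) <= 20) && !any(duplicated(v))
    wt <- wilcox.test(x, y, exact = exact, correct = TRUE)
    tibble(
      test = "wilcoxon",
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      df1 = NA_real_, df2 = NA_real_,
      n = length(v)
    )
  }
}

#' Pearson or Spearman correlation with validity checks
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 3`, each with
#'   nonzero variance.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' correlate(1:5, exp(1:5), method = "spearman") # 1
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    abort("'x' and 'y' must be paired vectors of length >= 3",
      class = "mxifhet_validation_error"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a zero-variance vector",
      class = "mxifhet_validation_error"
    )
  }
  cor(x, y, method = method)
}
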