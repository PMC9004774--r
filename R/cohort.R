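#' Classify body-mass index into weight classes
#'
#' Normal-weight: BMI < 25; overweight: 25 <= BMI < 30; obese:
#' BMI >= 30 (kg/m^2).
#'
#' @param bmi Numeric vector of BMI values (kg/m^2), all positive.
#' @return Factor with levels `normal-weight`, `overweight`, `obese`.
#' @export
#' @examples
#' classify_bmi(c(24.9, 25, 29.9, 30))
classify_bmi <- function(bmi) {
  if (!is.numeric(bmi) || any(is.na(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be positive and non-missing",
          class = "phosphosig_error_input")
  }
  cls <- ifelse(bmi < 25, "normal-weight", ifelse(bmi < 30, "overweight", "obese"))
  factor(cls, levels = c("normal-weight", "overweight", "obese"))
}

#' Infer menopausal status from age
#'
#' Premenopausal if age < 49 years, postmenopausal otherwise — the
#' proxy rule used for public cohorts lacking reported menopause.
#'
#' @param age Numeric vector of ages in years, all positive.
#' @return Factor with levels `pre`, `post`.
#' @export
#' @examples
#' classify_menopause(c(31, 48, 49))
classify_menopause <- function(age) {
  if (!is.numeric(age) || any(is.na(age)) || any(age <= 0)) {
    abort("`age` must be positive and non-missing",
          class = "phosphosig_error_input")
  }
  factor(ifelse(age < 49, "pre", "post"), levels = c("pre", "post"))
}

#' Assign BMI class and menopausal status to each clinical sample
#'
#' Samples lacking BMI (or age) are excluded and their count recorded
#' in the `n_excluded` attribute.
#'
#' @param clinical Tibble with `sample_id`, `age`, `bmi`.
#' @return Tibble: `sample_id`, `bmi_class`, `menopause`.
#' @export
assign_groups <- function(clinical) {
  needed <- c("sample_id", "age", "bmi")
  if (!all(needed %in% names(clinical))) {
    abort("clinical table must have sample_id, age and bmi columns",
          class = "phosphosig_error_input")
  }
  ok <- !is.na(clinical$bmi) & !is.na(clinical$age)
  out <- tibble(sample_id = clinical$sample_id[ok],
                bmi_class = classify_bmi(clinical$bmi[ok]),
                menopause = classify_menopause(clinical$age[ok]))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Compare signature scores between BMI classes with Wilcoxon rank-sum
#'
#' Runs a two-sided Wilcoxon rank-sum test for every unordered pair of
#' BMI classes, optionally within each menopause stratum. The p-value
#' is exact when the combined group size is at most 20 and there are no
#' ties, otherwise the normal approximation with continuity and tie
#' correction is used. Adjusted p-values (default Benjamini-Hochberg)
#' are computed across the reported family. Pairs where either group
#' has fewer than two samples are kept in the output but flagged
#' `skipped` with `NA` p-values.
#'
#' @param scores A [score_cohort()] result (or any tibble with
#'   `sample_id` and `final_score`).
#' @param assignment An [assign_groups()] result.
#' @param stratify_by_menopause Compare within each menopause stratum
#'   (default FALSE: overall).
#' @param p_adjust `"BH"` or `"none"`.
#' @return A tibble of class `"group_comparisons"`: `stratum`,
#'   `group1`, `group2`, `n1`, `n2`, `statistic`, `p.value`, `p.adj`,
#'   `median1`, `median2`, `direction`, `skipped`.
#' @export
compare_groups <- function(scores, assignment, stratify_by_menopause = FALSE,
                           p_adjust = c("BH", "none")) {
  p_adjust <- match.arg(p_adjust)
  score_col <- if ("final_score" %in% names(scores)) "final_score" else "score1"
  dat <- dplyr::inner_join(
    dplyr::select(scores, "sample_id", score = dplyr::all_of(score_col)),
    assignment, by = "sample_id")
  strata <- if (stratify_by_menopause) levels(dat$menopause) else "all"
  rows <- purrr::map(strata, function(st) {
    d <- if (identical(st, "all")) dat else dat[dat$menopause == st, ]
    classes <- levels(d$bmi_class)
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      x <- d$score[d$bmi_class == pr[1]]
      y <- d$score[d$bmi_class == pr[2]]
      if (length(x) < 2L || length(y) < 2L) {
        return(tibble(stratum = st, group1 = pr[1], group2 = pr[2],
                      n1 = length(x), n2 = length(y),
                      statistic = NA_real_, p.value = NA_real_,
                      median1 = if (length(x)) median(x) else NA_real_,
                      median2 = if (length(y)) median(y) else NA_real_,
                      direction = NA_character_, skipped = TRUE))
      }
      wt <- rank_sum_test(x, y)
      tibble(stratum = st, group1 = pr[1], group2 = pr[2],
             n1 = length(x), n2 = length(y),
             statistic = wt$statistic, p.value = wt$p.value,
             median1 = median(x), median2 = median(y),
             direction = dplyr::case_when(
               median(x) > median(y) ~ paste(pr[1], ">", pr[2]),
               median(x) < median(y) ~ paste(pr[1], "<", pr[2]),
               TRUE ~ "equal"),
             skipped = FALSE)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$p.adj <- if (p_adjust == "BH") p.adjust(rows$p.value, "BH") else rows$p.value
  rows <- dplyr::relocate(rows, "p.adj", .after = "p.value")
  if (any(rows$skipped)) {
    warn(sprintf("compare_groups: %d comparison(s) skipped (group with < 2 samples)",
                 sum(rows$skipped)))
  }
  class(rows) <- c("group_comparisons", class(rows))
  rows
}

# two-sided rank-sum: exact for combined n <= 20 without ties, else
# normal approximation with continuity + tie correction
rank_sum_test <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Summarize scores by group and tabulate comparisons
#'
#' @param scores A [score_cohort()] result.
#' @param assignment An [assign_groups()] result.
#' @param comparisons Optional [compare_groups()] result; `NULL` gives
#'   a summary-only report.
#' @return An object of class `"cohort_report"`: list of tibbles
#'   `summary` (per-group n, median, q1, q3 of the final score) and
#'   `comparisons`.
#' @export
build_report <- function(scores, assignment, comparisons = NULL) {
  score_col <- if ("final_score" %in% names(scores)) "final_score" else "score1"
  dat <- dplyr::inner_join(
    dplyr::select(scores, "sample_id", score = dplyr::all_of(score_col)),
    assignment, by = "sample_id")
  summary <- dat |>
    dplyr::group_by(group = .data$bmi_class) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$score),
                     q1 = unname(quantile(.data$score, 0.25)),
                     q3 = unname(quantile(.data$score, 0.75)),
                     .groups = "drop") |>
    dplyr::mutate(group = as.character(.data$group))
  comparisons <- if (is.null(comparisons)) {
    tibble(stratum = character(), group1 = character(), group2 = character(),
           n1 = integer(), n2 = integer(), statistic = double(),
           p.value = double(), p.adj = double(), median1 = double(),
           median2 = double(), direction = character(), skipped = logical())
  } else {
    as_tibble(comparisons)
  }
  structure(list(summary = summary, comparisons = comparisons),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n-- group summary --\n")
  print(x$summary)
  if (nrow(x$comparisons)) {
    cat("-- pairwise comparisons --\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Write / read a cohort report as TSV files
#'
#' Writes `<stem>_summary.tsv` and `<stem>_comparisons.tsv`.
#'
#' @param report A `"cohort_report"`.
#' @param stem Output path stem.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, stem) {
  paths <- paste0(stem, c("_summary.tsv", "_comparisons.tsv"))
  write_tsv_exact(report$summary, paths[1])
  write_tsv_exact(report$comparisons, paths[2])
  invisible(paths)
}

#' @rdname write_report
#' @export
read_report <- function(stem) {
  tsv <- function(p) readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  structure(list(summary = tsv(paste0(stem, "_summary.tsv")),
                 comparisons = tsv(paste0(stem, "_comparisons.tsv"))),
            class = "cohort_report")
}
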