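#' Full staining-analysis report for a TMA cohort
#'
#' Runs the complete validation battery on an immunohistochemistry
#' cohort:
#'
#' * case vs reference contingency table of the binarized stain, with
#'   Fisher's exact p (the primary test: the smallest expected cell of
#'   the published table is below 5), Pearson chi-square for
#'   transparency, and the crude odds ratio with Woolf interval;
#' * the case vs reference score-level (0-3) table with two candidate
#'   tests — chi-square on the 2x4 table and a score rank-sum — since
#'   neither is canonical for ordinal staining grades;
#' * diabetes-stratified three-group analysis (reference, case without
#'   diabetes, case with diabetes; cases of unknown diabetes status are
#'   excluded): Kruskal-Wallis on the binary indicator and on the 0-3
#'   score, and the three pairwise score rank-sum tests with raw and
#'   Bonferroni-adjusted p-values;
#' * a crude logistic fit of the binarized stain on case status, whose
#'   odds ratio matches the contingency-table odds ratio exactly in the
#'   saturated 2x2 case.
#'
#' @param cohort Cohort data frame with columns `group`, `score`, `dm`
#'   (logical, `NA` allowed).
#' @param case_group,reference_group Labels in `cohort$group` defining
#'   the contrast (defaults `"PaC"` vs `"normal"`).
#' @param cutoff Staining positivity cutoff passed to [binarize_stain()].
#' @return An object of class `tma_report` (a named list of tables,
#'   [test_result()]s, the odds-ratio result, the pairwise data frame and
#'   the logistic fit).
#' @export
tma_report <- function(cohort, case_group = "PaC",
                       reference_group = "normal", cutoff = 1L) {
  stopifnot(all(c("group", "score", "dm") %in% names(cohort)))
  cohort <- cohort[cohort$group %in% c(case_group, reference_group), ,
                   drop = FALSE]
  if (nrow(cohort) == 0L) stop("no samples in the requested groups", call. = FALSE)
  cohort$positive <- binarize_stain(cohort$score, cutoff)
  grp <- factor(cohort$group, levels = c(reference_group, case_group))

  # --- binary contrast (case vs reference) ------------------------------
  binary_tab <- build_contingency(
    cohort, as.character(grp), factor(cohort$positive, levels = c(1, 0)))
  fisher <- fisher_exact_2x2(binary_tab)
  chi2 <- pearson_chi2(binary_tab)
  # odds of positive staining in the case group relative to reference:
  # rows = (case, reference), cols = (positive, negative)
  or_tab <- rbind(as.numeric(binary_tab[case_group, c("1", "0")]),
                  as.numeric(binary_tab[reference_group, c("1", "0")]))
  or <- odds_ratio_woolf(or_tab)

  # --- score-level contrast (method for ordinal grades is not canonical) -
  score_tab <- build_contingency(
    cohort, as.character(grp), factor(cohort$score, levels = 0:3))
  score_chi2 <- pearson_chi2(score_tab[, colSums(score_tab) > 0, drop = FALSE])
  score_ranksum <- wilcoxon_rank_sum(
    cohort$score[grp == reference_group], cohort$score[grp == case_group])

  # --- diabetes-stratified three-group analysis -------------------------
  stratum <- ifelse(cohort$group == reference_group, reference_group,
                    ifelse(is.na(cohort$dm), NA_character_,
                           ifelse(cohort$dm, paste0(case_group, "_DM"),
                                  paste0(case_group, "_no_DM"))))
  strata_levels <- c(reference_group, paste0(case_group, "_no_DM"),
                     paste0(case_group, "_DM"))
  keep <- !is.na(stratum)
  by_stratum <- split(cohort$score[keep],
                      factor(stratum[keep], levels = strata_levels))
  strata <- list(
    n_excluded_unknown_dm = sum(!keep),
    score_table = build_contingency(
      cohort[keep, , drop = FALSE],
      factor(stratum[keep], levels = strata_levels),
      factor(cohort$score[keep], levels = 0:3)),
    kw_binary = kruskal_wallis(lapply(by_stratum, function(s)
      binarize_stain(s, cutoff))),
    kw_score = kruskal_wallis(by_stratum)
  )
  pairs <- utils::combn(strata_levels, 2L, simplify = FALSE)
  raw_p <- vapply(pairs, function(pr)
    wilcoxon_rank_sum(by_stratum[[pr[1]]], by_stratum[[pr[2]]])$p_value,
    numeric(1))
  adj <- bonferroni(raw_p)
  strata$pairwise <- data.frame(
    group_a = vapply(pairs, `[`, character(1), 1L),
    group_b = vapply(pairs, `[`, character(1), 2L),
    p_raw = adj$raw, p_bonferroni = adj$adjusted,
    stringsAsFactors = FALSE)

  # --- crude logistic: stain ~ case status ------------------------------
  design <- cbind(`(Intercept)` = 1, case = as.integer(grp == case_group))
  logistic <- logistic_fit(cohort$positive, design)

  structure(list(
    case_group = case_group, reference_group = reference_group,
    cutoff = cutoff, n = nrow(cohort),
    binary_table = binary_tab, fisher = fisher, chi2 = chi2,
    odds_ratio = or,
    score_table = score_tab, score_chi2 = score_chi2,
    score_ranksum = score_ranksum,
    strata = strata,
    logistic = logistic
  ), class = "tma_report")
}

#' @export
print.tma_report <- function(x, ...) {
  cat(sprintf("TMA staining report: %s vs %s (n = %d, positivity = score >= %d)\n\n",
              x$case_group, x$reference_group, x$n, x$cutoff))
  cat("Binary staining (rows = group, cols = positive/negative):\n")
  print(unclass(x$binary_table))
  cat("  "); print(x$fisher)
  cat("  "); print(x$chi2)
  cat("  "); print(x$odds_ratio)
  cat("\nScore-level (0-3) comparison:\n")
  cat("  "); print(x$score_chi2)
  cat("  "); print(x$score_ranksum)
  cat(sprintf("\nDiabetes-stratified analysis (%d unknown-DM cases excluded):\n",
              x$strata$n_excluded_unknown_dm))
  cat("  "); print(x$strata$kw_binary)
  cat("  "); print(x$strata$kw_score)
  cat("  Pairwise score rank-sum tests:\n")
  print.data.frame(x$strata$pairwise, row.names = FALSE, digits = 3)
  cat("\nCrude logistic fit of positivity on case status:\n")
  print(x$logistic)
  invisible(x)
}

#' Serialize a TMA report to machine-readable JSON
#'
#' Writes the numeric core of a [tma_report()] (tables, statistics, raw
#' and adjusted p-values, odds ratio and interval) as a JSON file for
#' downstream checking.
#'
#' @param report A `tma_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tma_report_json <- function(report, path) {
  stopifnot(inherits(report, "tma_report"))
  tr <- function(t) list(method = t$method, statistic = t$statistic,
                         df = t$df, p_value = t$p_value)
  payload <- list(
    contrast = paste(report$case_group, "vs", report$reference_group),
    n = report$n,
    cutoff = report$cutoff,
    binary_table = as.data.frame.matrix(unclass(report$binary_table)),
    fisher = tr(report$fisher),
    chi2 = tr(report$chi2),
    odds_ratio = report$odds_ratio[c("odds_ratio", "ci_low", "ci_high",
                                     "level", "haldane_corrected")],
    score_chi2 = tr(report$score_chi2),
    score_ranksum = tr(report$score_ranksum),
    kw_binary = tr(report$strata$kw_binary),
    kw_score = tr(report$strata$kw_score),
    pairwise = report$strata$pairwise,
    logistic = as.data.frame(report$logistic)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
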