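#' Hypothesis-test result container
#'
#' Uniform return value for all test wrappers in the package.
#'
#' @param method Method label.
#' @param statistic Test statistic (may be `NA` for exact tests).
#' @param df Degrees of freedom or `NA`.
#' @param p_value P-value in \[0, 1\].
#' @param adjusted Whether `p_value` is multiplicity-adjusted.
#' @param n_comparisons Number of comparisons behind an adjusted p, else
#'   `NA`.
#' @return An object of class `test_result`.
#' @export
test_result <- function(method, statistic = NA_real_, df = NA_integer_,
                        p_value, adjusted = FALSE,
                        n_comparisons = NA_integer_) {
  stopifnot(p_value >= 0, p_value <= 1, !adjusted || !is.na(n_comparisons))
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, adjusted = adjusted,
                 n_comparisons = n_comparisons),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method)
  if (!is.na(x$statistic)) cat(sprintf(": statistic = %.4g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %d", as.integer(x$df)))
  cat(sprintf(", p = %.4g", x$p_value))
  if (x$adjusted) cat(sprintf(" (Bonferroni-adjusted, m = %d)", x$n_comparisons))
  cat("\n")
  invisible(x)
}

#' Binarize an immunohistochemistry staining score
#'
#' Positive staining is a score at or above the cutoff; the conventional
#' cutoff of 1 calls any staining (1-25% of cells or more) positive.
#'
#' @param score Integer vector of pathologist scores, each in 0..3.
#' @param cutoff Positivity cutoff (default 1).
#' @return Integer vector of 0/1 staining indicators; `NA` in, `NA` out.
#' @export
binarize_stain <- function(score, cutoff = 1L) {
  ok <- is.na(score) | (score %in% 0:3)
  if (!all(ok)) {
    stop("staining score outside 0-3: ",
         paste(unique(score[!ok]), collapse = ", "), call. = FALSE)
  }
  as.integer(score >= cutoff)
}

#' Assemble an analysis cohort by diagnosis exclusion
#'
#' Removes samples whose `diagnosis_label` falls in the exclusion set
#' (e.g. chronic pancreatitis or metastases when the contrast of interest
#' is adenocarcinoma versus normal) and tallies the exclusions per label.
#'
#' @param samples Cohort data frame with a `diagnosis_label` column.
#' @param exclusion_labels Character vector of labels to drop.
#' @return A list with `included` (the retained data frame) and
#'   `excluded_tally` (named integer vector of dropped counts per label).
#' @export
assemble_cohort <- function(samples, exclusion_labels = character()) {
  stopifnot(is.data.frame(samples), "diagnosis_label" %in% names(samples))
  drop <- samples$diagnosis_label %in% exclusion_labels
  tally <- table(factor(samples$diagnosis_label[drop],
                        levels = sort(unique(samples$diagnosis_label[drop]))))
  list(included = samples[!drop, , drop = FALSE],
       excluded_tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Cross-tabulate two sample factors
#'
#' Builds the contingency table of two per-sample variables; samples with
#' a missing value in either variable are dropped and their count is
#' recorded in the `n_dropped` attribute.
#'
#' @param samples Cohort data frame.
#' @param row_factor,col_factor Column name (or a vector of length
#'   `nrow(samples)`) defining rows / columns.
#' @return A `table` with attribute `n_dropped`.
#' @export
build_contingency <- function(samples, row_factor, col_factor) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) stop("empty cohort", call. = FALSE)
  get <- function(f) {
    if (is.character(f) && length(f) == 1L && f %in% names(samples)) samples[[f]]
    else if (length(f) == nrow(samples)) f
    else stop("factor must be a column name or a full-length vector",
              call. = FALSE)
  }
  r <- get(row_factor); c_ <- get(col_factor)
  keep <- !is.na(r) & !is.na(c_)
  tab <- table(r[keep], c_[keep])
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule: with margins fixed, the
#' p-value is the sum of hypergeometric probabilities of all tables no
#' more probable than the observed one (the convention of
#' [stats::fisher.test()], which performs the computation). A table with
#' a zero margin carries no information about association and returns
#' p = 1 with a warning.
#'
#' @param tab 2x2 matrix or table of non-negative integer counts.
#' @return A [test_result()] (statistic slot unused: the test is exact).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as_count_matrix(tab, 2L, 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: Fisher p set to 1", call. = FALSE)
    return(test_result("Fisher's exact test (two-sided)", p_value = 1))
  }
  ft <- stats::fisher.test(tab)
  # fisher.test can exceed 1 by rounding when the whole support is counted
  test_result("Fisher's exact test (two-sided)", p_value = min(ft$p.value, 1))
}

#' Pearson chi-square test of independence
#'
#' Statistic `sum((O - E)^2 / E)` on an r x c table, df `(r-1)(c-1)`,
#' upper-tail chi-square p; no continuity correction.
#'
#' @param tab r x c matrix or table of non-negative integer counts with
#'   positive margins.
#' @return A [test_result()].
#' @export
pearson_chi2 <- function(tab) {
  tab <- as_count_matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined for a table with a zero margin",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("Pearson chi-square", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value)
}

as_count_matrix <- function(tab, nr = NULL, nc = NULL) {
  m <- as.matrix(unclass(tab))
  if (!is.null(nr) && !identical(dim(m), c(nr, nc))) {
    stop(sprintf("expected a %dx%d table", nr, nc), call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  dimnames(m) <- NULL
  m
}

#' Wilcoxon rank-sum test (tie-corrected normal approximation)
#'
#' Two-sided p from `z = (W - mu) / sigma`, where `W` is the rank sum of
#' the first group with average ranks for ties,
#' `mu = n1 (N + 1) / 2`, and the tie-corrected variance is
#' `sigma^2 = (n1 n2 / 12) * ((N + 1) - sum(t^3 - t) / (N (N - 1)))`
#' over tie-group sizes `t`. No continuity correction is applied. With
#' heavily tied ordinal data (like 0-3 staining scores) the tie
#' correction is essential; without it the variance is overstated.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A [test_result()] whose statistic is `z`; identical values
#'   across both groups give z = 0, p = 1.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  pooled <- c(group_a, group_b)
  r <- rank(pooled, ties.method = "average")
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  t_sizes <- table(pooled)
  tie_term <- sum(t_sizes^3 - t_sizes) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(test_result("Wilcoxon rank-sum (normal approximation)",
                       statistic = 0, p_value = 1))
  }
  z <- (w - mu) / sqrt(sigma2)
  test_result("Wilcoxon rank-sum (normal approximation)", statistic = z,
              p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kruskal-Wallis rank test for k groups
#'
#' The H statistic with average ranks and the tie-correction divisor
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`, referred to chi-square with k - 1
#' degrees of freedom (delegates to [stats::kruskal.test()]). If every
#' observation is identical, C = 0 and the test is vacuous: H = 0, p = 1.
#'
#' @param groups List of k >= 2 non-empty numeric vectors.
#' @return A [test_result()].
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    return(test_result("Kruskal-Wallis rank test", statistic = 0,
                       df = length(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis rank test", statistic = unname(kt$statistic),
              df = unname(kt$parameter), p_value = kt$p.value)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1, retaining
#' the raw values and input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Data frame with columns `raw` and `adjusted` (and
#'   `n_comparisons` as an attribute).
#' @export
bonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  out <- data.frame(raw = p_values,
                    adjusted = stats::p.adjust(p_values, method = "bonferroni"))
  attr(out, "n_comparisons") <- length(p_values)
  out
}

#' Odds ratio with Woolf confidence interval
#'
#' Crude odds ratio `ad / bc` of a 2x2 table with the Woolf (log-scale
#' Wald) interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If
#' any cell is zero the Haldane-Anscombe correction adds 0.5 to every
#' cell (flagged in the result); a zero diagonal (a = d = 0 or
#' b = c = 0) leaves the ratio undefined and is an error.
#'
#' @param tab 2x2 matrix `rbind(c(a, b), c(d, c))` laid out as
#'   rows = exposure groups, columns = (event, no event): `a`/`b` are the
#'   first row's event and non-event counts.
#' @param level Confidence level (default 0.95).
#' @return Object of class `odds_ratio_result` with fields `odds_ratio`,
#'   `ci_low`, `ci_high`, `level`, `haldane_corrected`.
#' @export
odds_ratio_woolf <- function(tab, level = 0.95) {
  m <- as_count_matrix(tab, 2L, 2L)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  if ((a == 0 && d == 0) || (b == 0 && c_ == 0)) {
    stop("odds ratio undefined: a diagonal of the table is zero",
         call. = FALSE)
  }
  corrected <- any(m == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 level = level,
                 haldane_corrected = corrected),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("Odds ratio %.3g (%d%% CI %.3g-%.3g%s)\n", x$odds_ratio,
              round(100 * x$level), x$ci_low, x$ci_high,
              if (x$haldane_corrected) "; Haldane-Anscombe corrected" else ""))
  invisible(x)
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()], convergence tolerance 1e-8, at most 100
#' iterations) of a binary outcome on a design matrix that already
#' contains its intercept column. Complete separation — recognisable as
#' fitted probabilities pinned to 0/1 and diverging coefficients — is
#' reported through the `separation` flag rather than silently returning
#' the divergent estimates as if they were finite MLEs.
#'
#' @param outcome Binary (0/1 or logical) vector with both classes
#'   present.
#' @param predictors Numeric design matrix, `nrow = length(outcome)`,
#'   including an intercept column; column names label the terms.
#' @param level Confidence level for the Wald intervals.
#' @return Object of class `logistic_fit`: a data frame with one row per
#'   design column (`term`, `estimate`, `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`) and attributes `converged`, `separation`,
#'   `aliased` (terms dropped as non-identifiable), `n`.
#' @export
logistic_fit <- function(outcome, predictors, level = 0.95) {
  y <- as.integer(outcome)
  x <- as.matrix(predictors)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  if (nrow(x) <= ncol(x)) {
    stop("need more observations than predictors", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- fit$coefficients
  aliased <- names(coefs)[is.na(coefs)]
  # Wald SEs from the unscaled covariance of the final IRLS step,
  # honouring the QR pivot (rank-deficient designs)
  qr_r <- fit$qr
  p1 <- seq_len(qr_r$rank)
  cov_u <- chol2inv(qr_r$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, length(coefs))
  se[qr_r$pivot[p1]] <- sqrt(diag(cov_u))
  if (any(abs(coefs[!is.na(coefs)]) > 15)) separation <- TRUE
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    term = names(coefs),
    estimate = unname(coefs),
    se = se,
    odds_ratio = exp(unname(coefs)),
    ci_low = exp(unname(coefs) - z * se),
    ci_high = exp(unname(coefs) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(coefs) / se)),
    stringsAsFactors = FALSE
  )
  structure(out, converged = fit$converged, separation = separation,
            aliased = aliased, n = length(y),
            class = c("logistic_fit", "data.frame"))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d%s%s)\n", attr(x, "n"),
              if (!attr(x, "converged")) ", NOT converged" else "",
              if (attr(x, "separation")) ", SEPARATION detected" else ""))
  if (length(attr(x, "aliased"))) {
    cat("  aliased (dropped):", paste(attr(x, "aliased"), collapse = ", "), "\n")
  }
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-group cohort summary with bivariate tests
#'
#' Clinical-table style summary: continuous variables as
#' `median (min-max)` compared by the tie-corrected rank-sum test (two
#' groups) or Kruskal-Wallis (more), categorical/binary variables as
#' `count (%)` compared by Fisher's exact test. Each variable is analysed
#' on its complete cases; the per-variable denominators are part of the
#' output since missingness varies between variables.
#'
#' @param samples Cohort data frame.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param continuous,categorical Character vectors naming the columns to
#'   summarise each way (defaults cover the standard cohort layout).
#' @return Data frame with one row per variable: `variable`, one summary
#'   column per group, `p_value`, `method`, `n_used`.
#' @export
summarize_cohort <- function(samples, group_col = "group",
                             continuous = "age",
                             categorical = c("sex", "tobacco", "alcohol", "dm")) {
  stopifnot(group_col %in% names(samples))
  g <- factor(samples[[group_col]])
  groups <- levels(g)
  fmt_num <- function(x) format(x, trim = TRUE, digits = 7)
  rows <- list()
  for (v in intersect(continuous, names(samples))) {
    x <- samples[[v]]
    keep <- !is.na(x) & !is.na(g)
    cells <- vapply(groups, function(gr) {
      xi <- x[keep & g == gr]
      if (!length(xi)) return("-")
      sprintf("%s (%s-%s)", fmt_num(stats::median(xi)),
              fmt_num(min(xi)), fmt_num(max(xi)))
    }, character(1))
    p <- if (sum(keep) && length(unique(g[keep])) >= 2L) {
      by_g <- split(x[keep], droplevels(g[keep]))
      if (length(by_g) == 2L) wilcoxon_rank_sum(by_g[[1]], by_g[[2]])$p_value
      else kruskal_wallis(by_g)$p_value
    } else NA_real_
    rows[[v]] <- c(variable = v, cells,
                   p_value = p,
                   method = if (length(groups) == 2L) "rank-sum" else "Kruskal-Wallis",
                   n_used = sum(keep))
  }
  for (v in intersect(categorical, names(samples))) {
    x <- samples[[v]]
    keep <- !is.na(x) & !is.na(g)
    xf <- factor(x[keep])
    pos_level <- utils::tail(levels(xf), 1L)  # TRUE / "F" / 1
    cells <- vapply(groups, function(gr) {
      xi <- xf[g[keep] == gr]
      if (!length(xi)) return("-")
      n_pos <- sum(xi == pos_level)
      sprintf("%d (%.0f%%)", n_pos, 100 * n_pos / length(xi))
    }, character(1))
    p <- if (sum(keep) && nlevels(xf) >= 2L &&
             length(unique(g[keep])) >= 2L) {
      tab <- table(droplevels(g[keep]), xf)
      if (all(dim(tab) == 2L)) fisher_exact_2x2(tab)$p_value
      else stats::fisher.test(tab)$p.value
    } else NA_real_
    rows[[v]] <- c(variable = v, cells,
                   p_value = p, method = "Fisher exact", n_used = sum(keep))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$p_value <- as.numeric(out$p_value)
  out$n_used <- as.integer(out$n_used)
  out
}
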