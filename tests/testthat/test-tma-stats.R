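# staining-score vectors of the published cohort, by stratum
fixture_scores <- function() {
  coh <- build_paper_cohort()
  list(normal = coh$score[coh$group == "normal"],
       pac = coh$score[coh$group == "PaC"],
       pac_no_dm = coh$score[!is.na(coh$stratum) & coh$stratum == "PaC_no_DM"],
       pac_dm = coh$score[!is.na(coh$stratum) & coh$stratum == "PaC_DM"])
}

test_that("stain binarization follows the score >= cutoff rule", {
  expect_identical(binarize_stain(0L), 0L)
  expect_identical(binarize_stain(1L), 1L)
  expect_identical(binarize_stain(2L, cutoff = 3L), 0L)
  expect_identical(binarize_stain(c(0, 1, 2, 3, NA)),
                   c(0L, 1L, 1L, 1L, NA_integer_))
  expect_error(binarize_stain(4L), "outside 0-3")
})

test_that("cohort assembly removes excluded diagnoses and tallies them", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    diagnosis_label = c(rep("PaC", 5), rep("chronic pancreatitis", 3),
                        rep("normal", 2)),
    stringsAsFactors = FALSE)
  out <- assemble_cohort(samples, "chronic pancreatitis")
  expect_equal(nrow(out$included), 7L)
  expect_equal(out$excluded_tally, c(`chronic pancreatitis` = 3L))
  expect_identical(assemble_cohort(samples, character())$included, samples)
  all_out <- assemble_cohort(samples, unique(samples$diagnosis_label))
  expect_equal(nrow(all_out$included), 0L)
  expect_equal(sum(all_out$excluded_tally), 10L)
})

test_that("contingency tables cross-tabulate exactly and track dropped rows", {
  coh <- build_paper_cohort()
  coh$positive <- binarize_stain(coh$score)
  tab <- build_contingency(coh, "group", "positive")
  expect_equal(tab["normal", "1"], 1L, ignore_attr = TRUE)
  expect_equal(tab["normal", "0"], 20L, ignore_attr = TRUE)
  expect_equal(tab["PaC", "1"], 18L, ignore_attr = TRUE)
  expect_equal(tab["PaC", "0"], 42L, ignore_attr = TRUE)
  # three diabetes strata: positives 1 / 9 / 5
  tab3 <- build_contingency(coh, "stratum", "positive")
  expect_equal(attr(tab3, "n_dropped"), 13L)   # unknown-DM cases
  expect_equal(as.integer(tab3[c("normal", "PaC_no_DM", "PaC_DM"), "1"]),
               c(1L, 9L, 5L))
  one <- build_contingency(coh[1, ], "group", "positive")
  expect_equal(sum(one), 1L)
  expect_error(build_contingency(coh[0, ], "group", "positive"), "empty")
})

test_that("Fisher's exact test follows the minimum-likelihood enumeration rule", {
  # balanced table: no association, p exactly 1
  expect_equal(fisher_exact_2x2(rbind(c(2, 2), c(2, 2)))$p_value, 1)
  # 5-table support, checked against full enumeration
  t54 <- rbind(c(1, 4), c(3, 2))
  expect_equal(fisher_exact_2x2(t54)$p_value, enum_fisher_p(t54),
               tolerance = 1e-10)
  # random small tables vs the enumeration oracle
  set.seed(64)
  for (i in 1:40) {
    m <- matrix(rpois(4, 3), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p_value, enum_fisher_p(m),
                 tolerance = 1e-10)
  }
  expect_warning(res <- fisher_exact_2x2(rbind(c(0, 0), c(3, 2))),
                 "degenerate margin")
  expect_equal(res$p_value, 1)
})

test_that("Pearson chi-square equals the textbook formula", {
  # observed equal to expected: statistic 0, p 1
  t0 <- rbind(c(10, 20), c(20, 40))
  r0 <- pearson_chi2(t0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # published binary table: statistic ~ 5.52 on 1 df
  t2 <- rbind(c(1, 20), c(18, 42))
  r2 <- pearson_chi2(t2)
  expect_equal(r2$statistic, formula_chi2(t2), tolerance = 1e-10)
  expect_equal(round(r2$statistic, 2), 5.52)
  expect_equal(r2$df, 1L, ignore_attr = TRUE)
  # random rectangular tables vs the formula oracle
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(rpois(6, 8) + 1, 2, 3)
    r <- pearson_chi2(m)
    expect_equal(r$statistic, formula_chi2(m), tolerance = 1e-10)
    expect_equal(r$p_value, pchisq(formula_chi2(m), 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("the rank-sum test is tie-corrected and matches its references", {
  fx <- fixture_scores()
  # published contrast: diabetic cancer stratum vs normals
  r <- wilcoxon_rank_sum(fx$normal, fx$pac_dm)
  expect_equal(round(r$p_value, 3), 0.004)
  # agreement with the standard implementation of the same approximation
  w <- wilcox.test(fx$normal, fx$pac_dm, exact = FALSE, correct = FALSE)
  expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
  # identical groups: z = 0, p = 1
  same <- wilcoxon_rank_sum(c(1, 1, 2), c(1, 1, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(3, 3), c(3, 3, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("the rank-sum normal approximation tracks the exact permutation mid-p", {
  # groups of 4 small integers, exhaustive over all C(8,4) splits
  cases <- list(
    list(a = c(0, 0, 1, 2), b = c(1, 2, 2, 3)),   # tied staining scores
    list(a = c(1, 3, 5, 8), b = c(2, 4, 6, 7))    # untied values
  )
  for (cs in cases) {
    approx_p <- wilcoxon_rank_sum(cs$a, cs$b)$p_value
    exact_p <- perm_ranksum_p(cs$a, cs$b)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
  # the implemented formula agrees with the reference implementation of
  # the same approximation on random tied data to machine precision
  set.seed(90)
  for (i in 1:20) {
    a <- sample(0:3, sample(3:12, 1), replace = TRUE)
    b <- sample(0:3, sample(3:12, 1), replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is tie-corrected and collapses to the rank-sum for k = 2", {
  fx <- fixture_scores()
  groups3 <- list(fx$normal, fx$pac_no_dm, fx$pac_dm)
  bin3 <- lapply(groups3, binarize_stain)
  expect_equal(round(kruskal_wallis(bin3)$p_value, 2), 0.02)
  # H from scratch on small grouped data
  small <- list(c(1, 2, 2), c(0, 0, 1), c(2, 3, 3))
  expect_equal(kruskal_wallis(small)$statistic, formula_kw_h(small),
               tolerance = 1e-10)
  # identical groups: H = 0, p = 1
  flat <- kruskal_wallis(list(c(1, 1), c(1, 1, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # k = 2 consistency: H equals z^2 and the p-values coincide
  for (pair in list(list(fx$normal, fx$pac_dm),
                    list(c(0, 1, 1, 2), c(0, 0, 3)))) {
    z <- wilcoxon_rank_sum(pair[[1]], pair[[2]])
    kw <- kruskal_wallis(pair)
    expect_equal(kw$statistic, z$statistic^2, tolerance = 1e-9)
    expect_equal(kw$p_value, z$p_value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis chi-square p is close to the exact permutation mid-p", {
  for (groups in list(list(c(0, 1, 1), c(0, 0, 0, 2), c(2, 3, 1)),
                      list(c(0, 1, 1, 2), c(0, 0, 2, 2), c(1, 2, 3, 3)))) {
    approx_p <- kruskal_wallis(groups)$p_value
    expect_lt(abs(approx_p - perm_kw_p(groups)), 0.05)
  }
})

test_that("Bonferroni adjustment multiplies, caps and keeps order", {
  expect_equal(bonferroni(0.01)$adjusted, 0.01)
  adj <- bonferroni(c(0.004, 0.07, 0.09))
  expect_equal(adj$raw, c(0.004, 0.07, 0.09))
  expect_equal(adj$adjusted, c(0.012, 0.21, 0.27))
  expect_equal(bonferroni(c(0.5, 0.9))$adjusted, c(1, 1))
  expect_equal(attr(adj, "n_comparisons"), 3L)
})

test_that("Woolf odds ratios match hand evaluation and flag corrections", {
  # published binary table: cases (18 pos, 42 neg), normals (1 pos, 20 neg)
  or <- odds_ratio_woolf(rbind(c(18, 42), c(1, 20)))
  expect_equal(or$odds_ratio, (18 * 20) / (42 * 1))
  expect_equal(round(or$odds_ratio, 1), 8.6)
  se <- sqrt(1 / 18 + 1 / 42 + 1 / 1 + 1 / 20)
  expect_equal(or$ci_low, exp(log(or$odds_ratio) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(or$ci_low, 2), 1.07)
  expect_false(or$haldane_corrected)
  # balanced table: OR 1 with a log-symmetric interval
  o1 <- odds_ratio_woolf(rbind(c(5, 5), c(5, 5)))
  expect_equal(o1$odds_ratio, 1)
  expect_equal(log(o1$ci_high), -log(o1$ci_low), tolerance = 1e-12)
  # a zero cell triggers the Haldane-Anscombe correction
  oz <- odds_ratio_woolf(rbind(c(0, 5), c(3, 2)))
  expect_true(oz$haldane_corrected)
  expect_equal(oz$odds_ratio, (0.5 * 2.5) / (5.5 * 3.5))
  expect_error(odds_ratio_woolf(rbind(c(0, 5), c(3, 0))), "diagonal")
})

test_that("logistic regression reproduces the crude odds ratio and flags degeneracy", {
  coh <- build_paper_cohort()
  y <- binarize_stain(coh$score)
  x <- cbind(`(Intercept)` = 1, case = as.integer(coh$group == "PaC"))
  fit <- logistic_fit(y, x)
  # saturated 2x2 logistic: exp(slope) is exactly ad/bc
  expect_equal(fit$odds_ratio[fit$term == "case"], (18 * 20) / (42 * 1),
               tolerance = 1e-6)
  expect_true(attr(fit, "converged"))
  expect_false(attr(fit, "separation"))
  # constant predictor: non-identifiable, reported as aliased
  x_bad <- cbind(`(Intercept)` = 1, flat = rep(2, length(y)))
  fit_bad <- logistic_fit(y, x_bad)
  expect_true("flat" %in% attr(fit_bad, "aliased") ||
                any(is.na(fit_bad$estimate)))
  expect_error(logistic_fit(rep(1L, 10), cbind(1, rnorm(10))), "both classes")
  # complete separation is detected, not silently reported
  ys <- c(rep(0L, 8), rep(1L, 8))
  xs <- cbind(1, c(rnorm(8, -3), rnorm(8, 3)))
  expect_true(attr(logistic_fit(ys, xs), "separation"))
})

test_that("logistic regression recovers a known log odds ratio in simulation", {
  set.seed(555)
  ests <- ses <- numeric(50)
  for (i in 1:50) {
    x <- rbinom(500, 1, 0.5)
    p <- plogis(-0.5 + 1.0 * x)
    y <- rbinom(500, 1, p)
    fit <- logistic_fit(y, cbind(`(Intercept)` = 1, x = x))
    ests[i] <- fit$estimate[fit$term == "x"]
    ses[i] <- fit$se[fit$term == "x"]
  }
  se_mc <- sd(ests) / sqrt(50)
  expect_lt(abs(mean(ests) - 1.0), 3 * se_mc)
})

test_that("cohort summaries report median (range) and consistent rank-sum p-values", {
  s3 <- data.frame(group = "A", age = c(26, 59, 79), sex = "F",
                   stringsAsFactors = FALSE)
  out <- summarize_cohort(s3, continuous = "age", categorical = character())
  expect_equal(out$A[out$variable == "age"], "59 (26-79)")
  # two identical groups: every p is 1
  twin <- data.frame(group = rep(c("A", "B"), each = 4),
                     age = rep(c(50, 60, 70, 80), 2),
                     sex = rep(c("F", "M", "F", "M"), 2),
                     stringsAsFactors = FALSE)
  out2 <- summarize_cohort(twin, continuous = "age", categorical = "sex")
  expect_true(all(out2$p_value == 1))
  # the continuous p is the package's own rank-sum test
  set.seed(77)
  coh <- data.frame(group = rep(c("A", "B"), each = 20),
                    age = c(rnorm(20, 55, 8), rnorm(20, 65, 8)),
                    stringsAsFactors = FALSE)
  out3 <- summarize_cohort(coh, continuous = "age", categorical = character())
  direct <- wilcoxon_rank_sum(coh$age[coh$group == "A"],
                              coh$age[coh$group == "B"])
  expect_equal(out3$p_value[out3$variable == "age"], direct$p_value)
})

test_that("permuting sample order changes no reported statistic", {
  coh <- build_paper_cohort()
  set.seed(41)
  perm <- coh[sample(nrow(coh)), ]
  a <- tma_report(coh)
  b <- tma_report(perm)
  expect_equal(a$fisher$p_value, b$fisher$p_value)
  expect_equal(a$odds_ratio$odds_ratio, b$odds_ratio$odds_ratio)
  expect_equal(a$strata$kw_score$statistic, b$strata$kw_score$statistic)
  expect_equal(a$strata$pairwise$p_raw, b$strata$pairwise$p_raw)
  expect_equal(a$logistic$estimate, b$logistic$estimate)
})
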