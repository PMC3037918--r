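#' Configuration for a synthetic expression compendium
#'
#' Describes a multi-disease, multi-dataset compendium with known ground
#' truth. Each dataset is one "study": a gene-by-sample matrix with a
#' disease group and a normal group. Baseline expression is log-scale
#' Gaussian with gene-specific means; for each disease the configured
#' planted genes are shifted upward in disease samples only, by
#' `effect_shift` standard deviations of the baseline noise. A fraction of
#' genes is dropped independently per dataset, emulating incomplete
#' platform coverage across studies.
#'
#' @param n_diseases Number of disease concepts.
#' @param n_datasets_per_disease Datasets generated per disease.
#' @param n_genes Size of the gene universe (ids `g0001`, `g0002`, ...).
#' @param n_samples_per_group Samples in each of the disease and normal
#'   groups of every dataset.
#' @param planted_up_genes Named list mapping disease label to a character
#'   vector of genes upregulated in that disease; may be empty.
#' @param effect_shift Mean upward shift of planted genes in disease
#'   samples, in units of `noise_sd`. `0` is the null configuration.
#' @param noise_sd Standard deviation of the per-measurement Gaussian
#'   noise on the log scale.
#' @param missing_gene_fraction Probability that any given gene is absent
#'   from any given dataset's platform, independently.
#' @param seed Integer seed; the whole compendium is reproducible from it.
#' @return A validated `compendium_config` list. Disease labels are
#'   `disease01`, `disease02`, ... unless `planted_up_genes` names others.
#' @export
compendium_config <- function(n_diseases = 3L,
                              n_datasets_per_disease = 4L,
                              n_genes = 1000L,
                              n_samples_per_group = 10L,
                              planted_up_genes = list(),
                              effect_shift = 2,
                              noise_sd = 1,
                              missing_gene_fraction = 0.1,
                              seed = 1L) {
  stopifnot(n_diseases >= 1L, n_datasets_per_disease >= 1L,
            n_genes >= 2L, n_samples_per_group >= 1L,
            effect_shift >= 0, noise_sd > 0,
            missing_gene_fraction >= 0, missing_gene_fraction < 1)
  universe <- sprintf("g%04d", seq_len(n_genes))
  if (length(planted_up_genes) &&
      (is.null(names(planted_up_genes)) || any(names(planted_up_genes) == ""))) {
    stop("planted_up_genes must be a named list (disease -> genes)",
         call. = FALSE)
  }
  # diseases named in planted_up_genes come first; pad with generic labels
  diseases <- names(planted_up_genes)
  pad <- setdiff(sprintf("disease%02d", seq_len(n_diseases)), diseases)
  diseases <- c(diseases, pad)[seq_len(max(n_diseases, length(planted_up_genes)))]
  bad <- setdiff(unlist(planted_up_genes), universe)
  if (length(bad)) {
    stop("planted gene(s) outside the gene universe: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_diseases = as.integer(length(diseases)),
    diseases = diseases,
    n_datasets_per_disease = as.integer(n_datasets_per_disease),
    n_genes = as.integer(n_genes),
    universe = universe,
    n_samples_per_group = as.integer(n_samples_per_group),
    planted_up_genes = planted_up_genes,
    effect_shift = effect_shift,
    noise_sd = noise_sd,
    missing_gene_fraction = missing_gene_fraction,
    seed = as.integer(seed)
  ), class = "compendium_config")
}

#' Generate a synthetic expression compendium
#'
#' Draws the compendium described by a [compendium_config()]: for each
#' disease and dataset, gene-specific baseline means (Normal(7, 2) on the
#' log scale, per dataset), i.i.d. Gaussian noise, the configured upward
#' shift of planted genes in disease samples, and per-dataset random gene
#' dropout. Identical configs (including seed) give identical output.
#'
#' @param config A [compendium_config()].
#' @return A list of [expression_dataset()] objects, one per
#'   disease-dataset pair, named by dataset id.
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "compendium_config"))
  set.seed(config$seed)
  out <- list()
  for (disease in config$diseases) {
    planted <- config$planted_up_genes[[disease]]
    for (k in seq_len(config$n_datasets_per_disease)) {
      id <- sprintf("%s_ds%02d", disease, k)
      keep <- config$universe[
        stats::runif(config$n_genes) >= config$missing_gene_fraction]
      if (length(keep) < 2L) keep <- config$universe[1:2]
      ng <- length(keep)
      n <- config$n_samples_per_group
      base_mean <- stats::rnorm(ng, mean = 7, sd = 2)
      mat <- matrix(stats::rnorm(ng * 2L * n, mean = base_mean,
                                 sd = config$noise_sd),
                    nrow = ng, ncol = 2L * n)
      shift_rows <- which(keep %in% planted)
      if (length(shift_rows) && config$effect_shift > 0) {
        mat[shift_rows, seq_len(n)] <- mat[shift_rows, seq_len(n)] +
          config$effect_shift * config$noise_sd
      }
      sample_ids <- sprintf("%s_s%02d", id, seq_len(2L * n))
      rownames(mat) <- keep
      colnames(mat) <- sample_ids
      ann <- data.frame(
        sample_id = sample_ids,
        disease_concept = disease,
        state = rep(c("disease", "normal"), each = n),
        tissue = "synthetic_tissue",
        stringsAsFactors = FALSE
      )
      out[[id]] <- expression_dataset(id, mat, ann)
    }
  }
  out
}

#' Generate susceptibility and biofluid gene lists
#'
#' Draws two gene lists from a universe without replacement at exact size
#' `round(fraction * length(universe))`, optionally forcing a given set
#' of genes into both lists so that planted screen candidates can be made
#' to survive the susceptibility and biofluid filters.
#'
#' @param universe Character vector of gene ids.
#' @param susceptibility_fraction,biofluid_fraction Fractions in (0, 1]
#'   giving each list's size relative to the universe.
#' @param overlap_with Character vector (subset of `universe`) forced into
#'   both lists; default none.
#' @param seed Integer seed.
#' @return A list with character vectors `susceptibility` and `biofluid`.
#' @export
generate_gene_lists <- function(universe, susceptibility_fraction,
                                biofluid_fraction,
                                overlap_with = character(), seed = 1L) {
  stopifnot(susceptibility_fraction > 0, susceptibility_fraction <= 1,
            biofluid_fraction > 0, biofluid_fraction <= 1)
  if (!all(overlap_with %in% universe)) {
    stop("overlap_with must be a subset of the universe", call. = FALSE)
  }
  set.seed(seed)
  draw <- function(fraction) {
    size <- max(round(fraction * length(universe)), length(overlap_with))
    rest <- setdiff(universe, overlap_with)
    extra <- sample(rest, size - length(overlap_with))
    sort(c(overlap_with, extra))
  }
  list(susceptibility = draw(susceptibility_fraction),
       biofluid = draw(biofluid_fraction))
}

#' Configuration for a synthetic TMA cohort
#'
#' Describes an immunohistochemistry tissue-microarray cohort: per-group
#' core counts, the multinomial distribution of the pathologist's 0-3
#' staining score within each group, and clinical covariates (age,
#' sex, tobacco, alcohol). Covariates are independent of the staining
#' score unless `age_score_slope` is nonzero, which adds `age_score_slope`
#' years of expected age per score point to exercise confounding analyses.
#'
#' @param group_sizes Named integer vector, group label -> core count.
#' @param score_probs Named list, group label -> probability 4-vector over
#'   scores 0..3 (each summing to 1 within 1e-9).
#' @param age_mean,age_sd Named numeric vectors (or scalars recycled to
#'   all groups) for the Gaussian age model.
#' @param p_female,p_tobacco,p_alcohol,p_dm Bernoulli prevalences, scalar
#'   or named per group.
#' @param age_score_slope Years of mean age added per staining score
#'   point (default 0: no confounding).
#' @param seed Integer seed.
#' @return A validated `tma_cohort_config` list.
#' @export
tma_cohort_config <- function(group_sizes,
                              score_probs,
                              age_mean = 62, age_sd = 10,
                              p_female = 0.5, p_tobacco = 0.5,
                              p_alcohol = 0.35, p_dm = 0.2,
                              age_score_slope = 0,
                              seed = 1L) {
  stopifnot(is.numeric(group_sizes), length(group_sizes) >= 1L,
            all(group_sizes >= 1), !is.null(names(group_sizes)))
  groups <- names(group_sizes)
  if (!setequal(names(score_probs), groups)) {
    stop("score_probs must be named by the same groups as group_sizes",
         call. = FALSE)
  }
  for (g in groups) {
    p <- score_probs[[g]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("score_probs[['%s']] must be 4 non-negative values summing to 1", g),
           call. = FALSE)
    }
  }
  per_group <- function(x) {
    if (length(x) == 1L) stats::setNames(rep(x, length(groups)), groups)
    else { stopifnot(setequal(names(x), groups)); x[groups] }
  }
  structure(list(
    group_sizes = stats::setNames(as.integer(group_sizes), groups),
    score_probs = score_probs[groups],
    age_mean = per_group(age_mean), age_sd = per_group(age_sd),
    p_female = per_group(p_female), p_tobacco = per_group(p_tobacco),
    p_alcohol = per_group(p_alcohol), p_dm = per_group(p_dm),
    age_score_slope = age_score_slope,
    seed = as.integer(seed)
  ), class = "tma_cohort_config")
}

#' Generate a synthetic TMA cohort
#'
#' Draws one tissue core per row: staining score from the group's
#' multinomial `score_probs`, age from the group's Gaussian (plus the
#' optional score-dependent shift), and Bernoulli sex/tobacco/alcohol/dm
#' flags. Group sizes are exact; everything is reproducible from the seed.
#'
#' @param config A [tma_cohort_config()].
#' @return A data frame with columns `sample_id`, `group`, `score`, `dm`,
#'   `age`, `sex`, `tobacco`, `alcohol`, `diagnosis_label`.
#' @export
generate_tma_cohort <- function(config) {
  stopifnot(inherits(config, "tma_cohort_config"))
  set.seed(config$seed)
  rows <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    score <- sample(0:3, n, replace = TRUE, prob = config$score_probs[[g]])
    age <- stats::rnorm(n, config$age_mean[[g]], config$age_sd[[g]]) +
      config$age_score_slope * score
    data.frame(
      group = g,
      score = score,
      dm = stats::rbinom(n, 1L, config$p_dm[[g]]) == 1L,
      age = round(age, 1L),
      sex = ifelse(stats::rbinom(n, 1L, config$p_female[[g]]) == 1L, "F", "M"),
      tobacco = stats::rbinom(n, 1L, config$p_tobacco[[g]]) == 1L,
      alcohol = stats::rbinom(n, 1L, config$p_alcohol[[g]]) == 1L,
      diagnosis_label = g,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = sprintf("core%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Deterministic published-cohort staining fixture
#'
#' Reconstructs, core for core, the staining-score distribution of the
#' published 81-sample pancreatic TMA analysis set: 21 histologically
#' normal cores (scores 0 x20, 2 x1) and 60 pancreatic adenocarcinoma
#' (PaC) cores (scores 0 x42, 1 x12, 2 x5, 3 x1). Diabetes status is known
#' for 47 of the PaC cores and splits them into PaC without diabetes
#' (n = 37; scores 0 x28, 1 x7, 2 x2) and PaC with diabetes (n = 10;
#' scores 0 x5, 1 x3, 2 x1, 3 x1); the remaining 13 PaC cores have
#' `dm = NA` and drop out of diabetes-stratified analyses. Clinical
#' covariates beyond the diabetes flag were published only in summary
#' form, so `age`, `sex`, `tobacco` and `alcohol` are `NA` here.
#'
#' @return A data frame in the [generate_tma_cohort()] layout, plus a
#'   `stratum` column with levels `normal`, `PaC_no_DM`, `PaC_DM` and `NA`
#'   for the unknown-diabetes PaC cores.
#' @export
build_paper_cohort <- function() {
  expand <- function(scores) rep(as.integer(names(scores)), times = scores)
  normal_scores <- expand(c(`0` = 20L, `2` = 1L))
  pac_nodm_scores <- expand(c(`0` = 28L, `1` = 7L, `2` = 2L))
  pac_dm_scores <- expand(c(`0` = 5L, `1` = 3L, `2` = 1L, `3` = 1L))
  # Table-2 marginal minus the two known-DM strata: the 13 unknown-DM cores
  pac_na_scores <- expand(c(`0` = 9L, `1` = 2L, `2` = 2L))
  df <- data.frame(
    group = c(rep("normal", length(normal_scores)),
              rep("PaC", length(pac_nodm_scores) + length(pac_dm_scores) +
                    length(pac_na_scores))),
    score = c(normal_scores, pac_nodm_scores, pac_dm_scores, pac_na_scores),
    dm = c(rep(FALSE, length(normal_scores)),
           rep(FALSE, length(pac_nodm_scores)),
           rep(TRUE, length(pac_dm_scores)),
           rep(NA, length(pac_na_scores))),
    stringsAsFactors = FALSE
  )
  df$stratum <- ifelse(df$group == "normal", "normal",
                       ifelse(is.na(df$dm), NA_character_,
                              ifelse(df$dm, "PaC_DM", "PaC_no_DM")))
  df$age <- NA_real_
  df$sex <- NA_character_
  df$tobacco <- NA
  df$alcohol <- NA
  df$diagnosis_label <- df$group
  cbind(sample_id = sprintf("core%03d", seq_len(nrow(df))), df,
        stringsAsFactors = FALSE)
}

#' Write / read a TMA cohort as CSV
#'
#' @param cohort Cohort data frame ([generate_tma_cohort()] layout).
#' @param path CSV file path.
#' @return `write_tma_cohort` invisibly returns `path`; `read_tma_cohort`
#'   returns the cohort data frame.
#' @export
write_tma_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tma_cohort
#' @export
read_tma_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("dm", "tobacco", "alcohol"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write / read newline-delimited gene lists
#'
#' @param genes Character vector of gene ids.
#' @param path File path.
#' @return `write_gene_list` invisibly returns `path`; `read_gene_list`
#'   returns the character vector (blank lines dropped).
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
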