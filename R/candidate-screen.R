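#' Configuration for the candidate biomarker screen
#'
#' Parameters of the filter cascade: the target disease whose upregulated
#' genes are sought, comparator diseases in which the genes must *not* be
#' upregulated, the rank-delta thresholds quantifying both conditions,
#' and how many top-ranked survivors become final candidates.
#'
#' @param target_disease Disease-concept label to screen for.
#' @param comparator_diseases Character vector of comparator labels (may
#'   be empty, making selectivity vacuous).
#' @param up_threshold Minimum target Delta to count as upregulated;
#'   default 0.10, the order of magnitude of top-ranked genes in compendia
#'   of this kind.
#' @param comparator_max_delta Maximum Delta allowed in any comparator
#'   disease; default 0 ("not upregulated"). Must be below `up_threshold`.
#' @param top_n Number of final candidates reported (default 10).
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(target_disease,
                          comparator_diseases = character(),
                          up_threshold = 0.10,
                          comparator_max_delta = 0,
                          top_n = 10L) {
  stopifnot(is.character(target_disease), length(target_disease) == 1L,
            up_threshold > comparator_max_delta, top_n >= 1L)
  structure(list(target_disease = target_disease,
                 comparator_diseases = comparator_diseases,
                 up_threshold = up_threshold,
                 comparator_max_delta = comparator_max_delta,
                 top_n = as.integer(top_n)),
            class = "screen_config")
}

# Case-folded, whitespace-stripped gene identifier key.
normalize_gene_id <- function(x) tolower(trimws(x))

#' Genes selectively upregulated in the target disease
#'
#' A gene passes if its target-disease Delta is at least
#' `config$up_threshold` and, in every comparator disease where it is
#' measured, its Delta does not exceed `config$comparator_max_delta`.
#' Genes unmeasured in one or more comparators are retained (platform
#' gaps should not disqualify a gene) but flagged.
#'
#' @param deltas A `gene_delta_table` (rows for the target and any
#'   comparator diseases, e.g. `rbind` of [aggregate_deltas()] results).
#' @param config A [screen_config()].
#' @return Character vector of passing genes, sorted, with attribute
#'   `measured_in_all_comparators` (named logical).
#' @export
selective_upregulation <- function(deltas, config) {
  stopifnot(is.data.frame(deltas), inherits(config, "screen_config"))
  tgt <- deltas[deltas$disease == config$target_disease, , drop = FALSE]
  if (nrow(tgt) == 0L) {
    stop(sprintf("target disease '%s' absent from the delta table",
                 config$target_disease), call. = FALSE)
  }
  up <- tgt$gene[tgt$delta >= config$up_threshold]
  keep <- character()
  fully_measured <- logical()
  for (g in up) {
    ok <- TRUE
    n_meas <- 0L
    for (cmp in config$comparator_diseases) {
      d <- deltas$delta[deltas$disease == cmp & deltas$gene == g]
      if (length(d) == 0L) next
      n_meas <- n_meas + 1L
      if (d > config$comparator_max_delta) { ok <- FALSE; break }
    }
    if (ok) {
      keep <- c(keep, g)
      fully_measured <- c(fully_measured,
                          n_meas == length(config$comparator_diseases))
    }
  }
  ord <- order(keep)
  structure(keep[ord],
            measured_in_all_comparators = stats::setNames(fully_measured[ord],
                                                          keep[ord]))
}

#' Intersect candidates with a susceptibility gene list
#'
#' Exact set intersection after identifier normalization (case folding
#' and whitespace stripping); of several input spellings mapping to the
#' same normalized id, the first is kept.
#'
#' @param genes Character vector of candidate genes.
#' @param susceptibility Character vector of disease-susceptibility genes.
#' @return The matching subset of `genes` (deduplicated, sorted).
#' @export
intersect_susceptibility <- function(genes, susceptibility) {
  key <- normalize_gene_id(genes)
  hit <- key %in% normalize_gene_id(susceptibility) & !duplicated(key)
  sort(genes[hit])
}

#' Restrict candidates to biofluid-detectable proteins
#'
#' Same contract as [intersect_susceptibility()] with a biofluid
#' (blood/urine proteome) list: a practical biomarker must be measurable
#' in an accessible fluid.
#'
#' @param genes Character vector of candidate genes.
#' @param biofluid Character vector of biofluid-detectable gene products.
#' @return The matching subset of `genes` (deduplicated, sorted).
#' @export
filter_biofluid <- function(genes, biofluid) {
  intersect_susceptibility(genes, biofluid)
}

#' Run the full candidate screen
#'
#' Scores every gene of the compendium for the target and comparator
#' diseases ([aggregate_deltas()]), applies the selectivity rule, the
#' susceptibility-list intersection and the biofluid filter, and returns
#' a per-gene report. Final candidates are the `top_n` genes by target
#' Delta (ties broken by gene id) among those passing all three stages.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param susceptibility,biofluid Character gene lists.
#' @param config A [screen_config()].
#' @param weighted Passed to [aggregate_deltas()].
#' @return A `candidate_report`: data frame sorted by target Delta
#'   descending with columns `gene`, `target_delta`, one
#'   `delta.<comparator>` column per comparator, `measured_in_all_comparators`,
#'   `passed_selectivity`, `in_susceptibility_list`, `in_biofluid_list`,
#'   `final_candidate`; the config is attached as attribute `config`.
#' @export
run_screen <- function(datasets, susceptibility, biofluid, config,
                       weighted = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  tgt <- aggregate_deltas(datasets, config$target_disease, weighted = weighted)
  if (nrow(tgt) == 0L) stop("no data for the target disease", call. = FALSE)
  cmp_tables <- lapply(config$comparator_diseases, function(d)
    aggregate_deltas(datasets, d, weighted = weighted))
  names(cmp_tables) <- config$comparator_diseases
  all_deltas <- do.call(rbind, c(list(tgt), unname(cmp_tables)))

  sel <- selective_upregulation(all_deltas, config)
  meas <- attr(sel, "measured_in_all_comparators")
  after_susc <- intersect_susceptibility(sel, susceptibility)
  after_bio <- filter_biofluid(after_susc, biofluid)

  report <- data.frame(gene = tgt$gene, target_delta = tgt$delta,
                       stringsAsFactors = FALSE)
  for (d in config$comparator_diseases) {
    cmp <- cmp_tables[[d]]
    report[[paste0("delta.", d)]] <-
      cmp$delta[match(report$gene, cmp$gene)]
  }
  report$measured_in_all_comparators <-
    ifelse(report$gene %in% sel, unname(meas[report$gene]), NA)
  report$passed_selectivity <- report$gene %in% sel
  report$in_susceptibility_list <-
    normalize_gene_id(report$gene) %in% normalize_gene_id(susceptibility)
  report$in_biofluid_list <-
    normalize_gene_id(report$gene) %in% normalize_gene_id(biofluid)

  survivors <- report$gene %in% after_bio
  ord_surv <- order(-report$target_delta[survivors], report$gene[survivors])
  final <- report$gene[survivors][ord_surv][seq_len(min(config$top_n, sum(survivors)))]
  report$final_candidate <- report$gene %in% final

  report <- report[order(-report$target_delta, report$gene), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "config") <- config
  class(report) <- c("candidate_report", "data.frame")
  report
}

#' @export
print.candidate_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Candidate screen: target '%s', %d comparator(s), %d genes scored\n",
              cfg$target_disease, length(cfg$comparator_diseases), nrow(x)))
  cat(sprintf("  selectivity (delta >= %.2f, comparators <= %.2f): %d genes\n",
              cfg$up_threshold, cfg$comparator_max_delta,
              sum(x$passed_selectivity)))
  cat(sprintf("  + susceptibility list: %d; + biofluid list: %d; final candidates: %d\n",
              sum(x$passed_selectivity & x$in_susceptibility_list),
              sum(x$passed_selectivity & x$in_susceptibility_list &
                    x$in_biofluid_list),
              sum(x$final_candidate)))
  fin <- x[x$final_candidate, c("gene", "target_delta"), drop = FALSE]
  if (nrow(fin)) {
    cat("Final candidates (by target delta):\n")
    print.data.frame(fin, row.names = FALSE)
  }
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' @param report A `candidate_report` from [run_screen()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
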