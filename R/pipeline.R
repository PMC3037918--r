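#' Derive reproducible per-stage seeds from one global seed
#'
#' Fans a single global seed out to independent stage seeds via one
#' deterministic draw, so that each pipeline stage is individually
#' reproducible and stages do not share RNG streams.
#'
#' @param seed Global integer seed.
#' @param n Number of stage seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
derive_stage_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full simulate / screen / TMA pipeline
#'
#' End-to-end orchestration: generates a synthetic compendium and gene
#' lists, runs the candidate screen, analyses a TMA cohort (the
#' deterministic published-table fixture by default, or a synthetic
#' cohort), and writes every report plus a JSON manifest recording the
#' configuration, seed and package version — enough to regenerate every
#' output file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed fanned out to the stages.
#' @param compendium A [compendium_config()]; its own seed is overridden
#'   by the derived stage seed. Defaults to a 3-disease compendium with
#'   5 candidate genes planted in the target disease.
#' @param screen A [screen_config()]; default targets the first disease
#'   with the others as comparators.
#' @param susceptibility_fraction,biofluid_fraction List sizes for
#'   [generate_gene_lists()]; the planted genes are forced into both
#'   lists so the cascade is exercised end to end.
#' @param tma_cohort `"paper-fixture"` (default) for
#'   [build_paper_cohort()], or a [tma_cohort_config()] for a synthetic
#'   cohort (seed again overridden by the stage seed).
#' @param cutoff Staining positivity cutoff.
#' @return Invisibly, a list with the `manifest` (also written to
#'   `manifest.json`), the `candidate_report` and the `tma_report`.
#' @export
run_end_to_end <- function(out_dir, seed = 1L,
                           compendium = NULL, screen = NULL,
                           susceptibility_fraction = 0.2,
                           biofluid_fraction = 0.2,
                           tma_cohort = "paper-fixture",
                           cutoff = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_stage_seeds(seed, 3L)

  if (is.null(compendium)) {
    compendium <- compendium_config(
      n_diseases = 3L, n_datasets_per_disease = 4L, n_genes = 500L,
      n_samples_per_group = 10L,
      planted_up_genes = list(disease01 = sprintf("g%04d", 1:5)),
      effect_shift = 3, seed = seeds[1L])
  } else {
    compendium$seed <- seeds[1L]
  }
  if (is.null(screen)) {
    screen <- screen_config(
      target_disease = compendium$diseases[1L],
      comparator_diseases = compendium$diseases[-1L])
  }

  datasets <- generate_compendium(compendium)
  planted <- unlist(compendium$planted_up_genes, use.names = FALSE)
  lists <- generate_gene_lists(compendium$universe,
                               susceptibility_fraction, biofluid_fraction,
                               overlap_with = planted, seed = seeds[2L])
  report <- run_screen(datasets, lists$susceptibility, lists$biofluid, screen)
  write_candidate_report(report, file.path(out_dir, "candidate_report.tsv"))
  write_gene_list(lists$susceptibility,
                  file.path(out_dir, "susceptibility_genes.txt"))
  write_gene_list(lists$biofluid, file.path(out_dir, "biofluid_genes.txt"))

  if (identical(tma_cohort, "paper-fixture")) {
    cohort <- build_paper_cohort()
    tma_mode <- "paper-fixture"
  } else {
    stopifnot(inherits(tma_cohort, "tma_cohort_config"))
    tma_cohort$seed <- seeds[3L]
    cohort <- generate_tma_cohort(tma_cohort)
    tma_mode <- "synthetic"
  }
  write_tma_cohort(cohort, file.path(out_dir, "tma_cohort.csv"))
  tma <- tma_report(cohort, cutoff = cutoff)
  write_tma_report_json(tma, file.path(out_dir, "tma_report.json"))
  summary_tsv <- summarize_cohort(cohort)
  utils::write.table(summary_tsv, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "markerscreen",
    version = as.character(utils::packageVersion("markerscreen")),
    seed = seed,
    stage_seeds = seeds,
    compendium = compendium[setdiff(names(compendium), "universe")],
    screen = unclass(screen),
    susceptibility_fraction = susceptibility_fraction,
    biofluid_fraction = biofluid_fraction,
    tma_mode = tma_mode,
    cutoff = cutoff,
    outputs = c("candidate_report.tsv", "susceptibility_genes.txt",
                "biofluid_genes.txt", "tma_cohort.csv", "tma_report.json",
                "cohort_summary.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, candidate_report = report,
                 tma_report = tma))
}

#' Command-line entry point
#'
#' Backs the `inst/cli/markerscreen.R` script. Subcommands:
#' `simulate` (write a synthetic compendium, gene lists and TMA cohort),
#' `screen` (run the candidate screen on a compendium directory),
#' `tma` (analyse a cohort CSV or the published-table fixture) and
#' `run-all` ([run_end_to_end()]). Arguments are `--key value` pairs;
#' see the script for the full listing.
#'
#' @param args Character vector of command-line arguments, the first
#'   being the subcommand.
#' @return Exit status: 0 on success, 2 on usage error (errors from the
#'   stages themselves propagate as R errors).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: markerscreen <simulate|screen|tma|run-all> [--key value ...]")
    return(2L)
  }
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L])
  out <- opts[["out"]]
  if (is.null(out)) { message("--out is required"); return(2L) }
  seed <- as.integer(opts[["seed"]] %||% 1L)
  switch(cmd,
    "simulate" = {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      seeds <- derive_stage_seeds(seed, 3L)
      cfg <- compendium_config(seed = seeds[1L])
      datasets <- generate_compendium(cfg)
      for (id in names(datasets)) {
        write_expression_dataset(datasets[[id]], file.path(out, id))
      }
      lists <- generate_gene_lists(cfg$universe, 0.2, 0.2, seed = seeds[2L])
      write_gene_list(lists$susceptibility,
                      file.path(out, "susceptibility_genes.txt"))
      write_gene_list(lists$biofluid, file.path(out, "biofluid_genes.txt"))
      write_tma_cohort(build_paper_cohort(),
                       file.path(out, "paper_fixture_cohort.csv"))
      0L
    },
    "screen" = {
      need <- c("compendium", "susceptibility", "biofluid", "target")
      if (!all(need %in% names(opts))) {
        message("screen needs --compendium --susceptibility --biofluid --target")
        return(2L)
      }
      files <- list.files(opts$compendium, pattern = "\\.tsv$",
                          full.names = TRUE)
      stems <- unique(sub("(\\.samples)?\\.tsv$", "", files))
      datasets <- lapply(stems, read_expression_dataset)
      comparators <- if (is.null(opts$comparators)) character()
        else strsplit(opts$comparators, ",", fixed = TRUE)[[1L]]
      cfg <- screen_config(
        target_disease = opts$target, comparator_diseases = comparators,
        up_threshold = as.numeric(opts[["threshold"]] %||% 0.10),
        top_n = as.integer(opts[["top-n"]] %||% 10L))
      rep <- run_screen(datasets, read_gene_list(opts$susceptibility),
                        read_gene_list(opts$biofluid), cfg)
      write_candidate_report(rep, out)
      0L
    },
    "tma" = {
      cohort <- if (isTRUE(opts[["paper-fixture"]] == "true") ||
                    is.null(opts[["cohort"]])) build_paper_cohort()
        else read_tma_cohort(opts[["cohort"]])
      rep <- tma_report(cohort, cutoff = as.integer(opts[["cutoff"]] %||% 1L))
      write_tma_report_json(rep, out)
      0L
    },
    "run-all" = {
      run_end_to_end(out, seed = seed)
      0L
    },
    { message("unknown subcommand: ", cmd); 2L }
  )
}

# "--key value" and bare "--flag" (-> "true") argument parser.
parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- "true"
      i <- i + 1L
    }
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
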