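#' Read and write sample measurement tables
#'
#' The on-disk dialect is a UTF-8 long-format CSV with header
#' `sample_id,analyte,measured,detected,concentration_mg_L,detection_limit_mg_L`.
#' Concentrations and detection limits are in mg/L; inputs recorded in ug/L
#' must be converted before entering the pipeline. Writing and re-reading a
#' cohort reproduces identical downstream results.
#'
#' @param path CSV path.
#' @return `read_samples()` returns a validated tibble; `write_samples()`
#'   returns `path` invisibly.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    abort_format(paste0("Sample table not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      analyte = readr::col_character(),
      measured = readr::col_logical(),
      detected = readr::col_logical(),
      concentration_mg_L = readr::col_double(),
      detection_limit_mg_L = readr::col_double()
    )
  )
  validate_samples(raw)
}

#' @rdname read_samples
#' @param samples A sample measurement table.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  readr::write_csv(samples, path)
  invisible(path)
}

run_manifest <- function(path, seed, config) {
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mcrscreen"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Wraps [simulate_cohort()]: writes `samples.csv`, the matching
#' `pd_table.csv` derived from the configuration, and a `manifest.json`
#' recording the seed and a hash of the configuration so any run can be
#' reproduced exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_samples,seed Passed to [groundwater_config()] when `config` is
#'   not supplied.
#' @param config Optional [cohort_config()] overriding the default.
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(out_dir, n_samples = 618, seed = 1L, config = NULL) {
  config <- config %||% groundwater_config(n_samples = n_samples, seed = seed)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- simulate_cohort(config)
  paths <- c(
    samples = file.path(out_dir, "samples.csv"),
    pd_table = file.path(out_dir, "pd_table.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(samples, paths[["samples"]])
  write_pd_table(config_pd_registry(config), paths[["pd_table"]])
  run_manifest(paths[["manifest"]], config$seed, config)
  inform(sprintf(
    "simulate: wrote %d measurements for %d samples to %s",
    nrow(samples), config$n_samples, out_dir
  ))
  invisible(paths)
}

#' Screen a cohort file and write per-mixture results
#'
#' Reads a sample table and a permitted-dose table, screens every mixture
#' under each requested non-detect case, and writes one
#' `results_<case>.csv` per case with columns
#' `sample_id,nd_case,hi,mhq,mcr,n_detects,n_analytes,top_chemical`.
#'
#' @param samples_path Path to a samples CSV ([read_samples()] dialect).
#' @param pd_path Path to a PD table CSV ([read_pd_table()] dialect);
#'   `NULL` uses the packaged registry.
#' @param out_dir Output directory.
#' @param nd_cases Non-detect cases to screen.
#' @param assumptions An [exposure_assumptions()] object.
#' @param parent_map_path Optional parent-map CSV for the PD table.
#' @return Named character vector of the files written, invisibly.
#' @export
run_screen <- function(samples_path, pd_path = NULL, out_dir = ".",
                       nd_cases = c("case1", "case2"),
                       assumptions = exposure_assumptions(),
                       parent_map_path = NULL) {
  samples <- read_samples(samples_path)
  registry <- if (is.null(pd_path)) {
    default_pd_registry(quiet = TRUE)
  } else {
    read_pd_table(pd_path, parent_map_path = parent_map_path, pd_warn_ceiling = Inf)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- screen_mixtures(samples, registry, assumptions, nd_case = nd_cases)
  paths <- character()
  for (case in unique(match_nd_case(nd_cases))) {
    p <- file.path(out_dir, paste0("results_", case, ".csv"))
    res <- dplyr::filter(results, .data$nd_case == case) |>
      dplyr::select(
        "sample_id", "nd_case", "hi", "mhq", "mcr",
        "n_detects", "n_analytes", "top_chemical"
      )
    readr::write_csv(res, p)
    paths[[case]] <- p
  }
  inform(sprintf(
    "screen: %d samples under %s", dplyr::n_distinct(samples$sample_id),
    paste(nd_cases, collapse = ", ")
  ))
  invisible(paths)
}

#' Run the full analysis on a cohort file and write the report
#'
#' Reads a sample table, runs [run_full_analysis()] and writes the report:
#' per-case mixture results, the exclusion log and counts, the cohort
#' count summary, the top-contributor table, per-case overall/threshold/
#' centile summaries, trend statistics, and a plain-text `summary.txt`.
#'
#' @inheritParams run_screen
#' @param config An [analysis_config()].
#' @return Named character vector of the files written, invisibly.
#' @export
run_analyze <- function(samples_path, pd_path = NULL, out_dir = ".",
                        assumptions = exposure_assumptions(),
                        config = analysis_config(),
                        parent_map_path = NULL) {
  samples <- read_samples(samples_path)
  registry <- if (is.null(pd_path)) {
    default_pd_registry(quiet = TRUE)
  } else {
    read_pd_table(pd_path, parent_map_path = parent_map_path, pd_warn_ceiling = Inf)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analysis <- run_full_analysis(samples, registry, assumptions, config)

  with(analysis$exclusion$counts, inform(sprintf(
    "analyze: %d samples in, %d removed (top-k rule), %d removed (min-detect rule), %d retained",
    n_in, n_removed_top_k, n_removed_min_detects, n_out
  )))

  paths <- c(
    results = file.path(out_dir, "mixture_results.csv"),
    exclusion_log = file.path(out_dir, "exclusion_log.csv"),
    counts = file.path(out_dir, "count_summary.csv"),
    top_contributors = file.path(out_dir, "top_contributors.csv"),
    overall = file.path(out_dir, "overall_summary.csv"),
    hi_split = file.path(out_dir, "hi_split.csv"),
    centiles = file.path(out_dir, "centile_summary.csv"),
    trends = file.path(out_dir, "trend_statistics.csv"),
    summary = file.path(out_dir, "summary.txt")
  )
  readr::write_csv(analysis$results, paths[["results"]])
  readr::write_csv(analysis$exclusion$log, paths[["exclusion_log"]])
  readr::write_csv(analysis$count_summary, paths[["counts"]])
  readr::write_csv(analysis$top_contributors, paths[["top_contributors"]])
  readr::write_csv(glance(analysis), paths[["overall"]])
  hi_split <- purrr::imap(analysis$per_case, function(pc, case) {
    dplyr::mutate(pc$hi_split$summary, nd_case = case, .before = 1)
  }) |> purrr::list_rbind()
  readr::write_csv(hi_split, paths[["hi_split"]])
  readr::write_csv(tidy(analysis), paths[["centiles"]])

  trend_rows <- purrr::imap(analysis$per_case, function(pc, case) {
    tr <- pc$trends
    grouped_row <- function(g, label) {
      tibble(
        nd_case = case, relationship = label,
        tau = if (g$insufficient) NA_real_ else g$trend$tau,
        p_value = if (g$insufficient) NA_real_ else g$trend$p_value,
        n = nrow(g$medians)
      )
    }
    dplyr::bind_rows(
      dplyr::mutate(tr$mcr_vs_hi, nd_case = case, relationship = "mcr_vs_hi", .before = 1),
      dplyr::mutate(tr$hi_vs_n, nd_case = case, relationship = paste0("hi_vs_", pc$size_key), .before = 1),
      dplyr::mutate(tr$mcr_vs_n, nd_case = case, relationship = paste0("mcr_vs_", pc$size_key), .before = 1),
      grouped_row(tr$hi_vs_n_grouped, paste0("hi_vs_", pc$size_key, "_grouped_median")),
      grouped_row(tr$mcr_vs_n_grouped, paste0("mcr_vs_", pc$size_key, "_grouped_median"))
    )
  }) |> purrr::list_rbind()
  readr::write_csv(trend_rows, paths[["trends"]])

  writeLines(utils::capture.output(print(analysis)), paths[["summary"]])
  invisible(paths)
}
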