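#' Select the mixtures whose HI falls in a centile band
#'
#' Mixtures are ranked by hazard index; the centile of the mixture of rank
#' `r` out of `N` is `100 * r / N`, and the subgroup contains the mixtures
#' whose centile lies in `(low, high]`. Ties in HI are broken by
#' `sample_id` so membership is deterministic. Published analyses of this
#' kind typically look at the 49-51st (typical), 94-96th (high-end) and
#' 98-100th (upper-bound) bands, each about 2% of the cohort.
#'
#' @param results An `mcr_screen` tibble (one non-detect case at a time).
#' @param low,high Centile bounds, `0 <= low < high <= 100`.
#' @return The member rows of `results`, with `hi_rank` and `hi_centile`
#'   columns appended.
#' @export
centile_subgroup <- function(results, low, high) {
  results <- as_tibble(results)
  if (nrow(results) == 0) {
    abort_domain("`results` must contain at least one mixture.")
  }
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || high > 100 || low >= high) {
    abort_domain("Centile bounds must satisfy 0 <= low < high <= 100.")
  }
  if (anyNA(results$hi)) {
    abort_domain("HI must be defined for every mixture.")
  }
  ord <- order(results$hi, results$sample_id)
  ranked <- results[ord, , drop = FALSE]
  ranked$hi_rank <- seq_len(nrow(ranked))
  ranked$hi_centile <- 100 * ranked$hi_rank / nrow(ranked)
  dplyr::filter(ranked, .data$hi_centile > low, .data$hi_centile <= high)
}

#' Summarise the MCR values of a subgroup
#'
#' Minimum, maximum and mean MCR of a set of mixtures. Mixtures with an
#' undefined MCR (all-zero HQ vector) are dropped with a warning and
#' reported in `n_undefined`.
#'
#' @param members A data frame with an `mcr` column (e.g. from
#'   [centile_subgroup()]).
#' @return A one-row tibble: `n_members`, `min_mcr`, `max_mcr`, `mean_mcr`,
#'   `n_undefined`.
#' @export
summarize_group <- function(members) {
  members <- as_tibble(members)
  if (nrow(members) == 0) {
    abort_domain("Cannot summarise an empty subgroup.")
  }
  undef <- is.na(members$mcr)
  if (any(undef)) {
    warn(sprintf(
      "%d mixture(s) with undefined MCR excluded from the subgroup summary.",
      sum(undef)
    ), class = "mcrscreen_undefined_mcr")
  }
  mcr <- members$mcr[!undef]
  if (length(mcr) == 0) {
    abort_domain("Subgroup has no mixture with a defined MCR.")
  }
  tibble(
    n_members = length(mcr),
    min_mcr = min(mcr),
    max_mcr = max(mcr),
    mean_mcr = mean(mcr),
    n_undefined = sum(undef)
  )
}

#' Split mixtures at a hazard-index threshold
#'
#' Partitions screened mixtures into those below and those at-or-above an
#' HI threshold (1 by default, the level at which cumulative exposure
#' reaches the protective dose). A mixture with HI exactly at the threshold
#' goes to the "above" side; the convention is arbitrary but fixed.
#'
#' @param results An `mcr_screen` tibble (one non-detect case).
#' @param threshold HI threshold, default 1.
#' @return A list with `below` and `above` (row subsets) and `summary`, a
#'   tibble of side, count, percentage, and min/max/mean MCR per side.
#' @export
split_by_hi <- function(results, threshold = 1) {
  results <- as_tibble(results)
  if (nrow(results) == 0) {
    abort_domain("`results` must contain at least one mixture.")
  }
  above <- results$hi >= threshold
  side_summary <- function(rows, label) {
    if (nrow(rows) == 0) {
      return(tibble(
        side = label, n = 0L, pct = 0,
        min_mcr = NA_real_, max_mcr = NA_real_, mean_mcr = NA_real_
      ))
    }
    mcr <- rows$mcr[!is.na(rows$mcr)]
    tibble(
      side = label, n = nrow(rows), pct = 100 * nrow(rows) / nrow(results),
      min_mcr = if (length(mcr)) min(mcr) else NA_real_,
      max_mcr = if (length(mcr)) max(mcr) else NA_real_,
      mean_mcr = if (length(mcr)) mean(mcr) else NA_real_
    )
  }
  list(
    below = results[!above, , drop = FALSE],
    above = results[above, , drop = FALSE],
    summary = dplyr::bind_rows(
      side_summary(results[!above, , drop = FALSE], "below"),
      side_summary(results[above, , drop = FALSE], "above")
    )
  )
}

#' Kendall rank-correlation trend test
#'
#' Kendall's tau-b (tie-corrected) with a two-sided p-value, the
#' nonparametric trend test used for MCR-vs-HI and size-vs-HI/MCR
#' relationships. The p-value is exact for small tie-free inputs and uses
#' the normal approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A tibble of class `mcr_trend`: `tau`, `p_value`, `n`.
#' @export
kendall_trend <- function(x, y) {
  if (length(x) != length(y)) {
    abort_domain("`x` and `y` must have equal length.")
  }
  if (length(x) < 2) {
    abort_domain("Need at least two observations for a trend test.")
  }
  out <- if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    # no variation in one variable: no trend, by convention tau = 0
    tibble(tau = 0, p_value = 1, n = length(x))
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  }
  class(out) <- c("mcr_trend", class(out))
  out
}

#' Kendall trend over grouped medians
#'
#' Mixtures are grouped by a size variable (number of detects for case 1,
#' number of analytes for case 2), the median of the chosen value is taken
#' within each group, and a Kendall trend test is run on the (group size,
#' median) pairs. Groups with fewer than `min_group` mixtures are dropped
#' first so that each median is reasonably stable.
#'
#' @param results An `mcr_screen` tibble (one non-detect case).
#' @param group_key `"n_detects"` or `"n_analytes"`.
#' @param value `"hi"` or `"mcr"` (undefined MCRs are dropped).
#' @param min_group Minimum group size for a median to be used (default 5).
#' @return A list of class `mcr_grouped_trend`: `medians` (tibble of
#'   surviving groups) and `trend` (an `mcr_trend`, or `NULL` with
#'   `insufficient = TRUE` when fewer than two groups survive).
#' @export
grouped_median_trend <- function(results, group_key = c("n_detects", "n_analytes"),
                                 value = c("hi", "mcr"), min_group = 5) {
  group_key <- match.arg(group_key)
  value <- match.arg(value)
  results <- as_tibble(results)
  if (nrow(results) == 0) {
    abort_domain("`results` must contain at least one mixture.")
  }
  vals <- results[[value]]
  keep <- !is.na(vals)
  medians <- tibble(n = results[[group_key]][keep], value = vals[keep]) |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      median_value = median(.data$value),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_members >= min_group) |>
    dplyr::arrange(.data$n)
  trend <- if (nrow(medians) >= 2) {
    kendall_trend(medians$n, medians$median_value)
  } else {
    NULL
  }
  structure(
    list(
      medians = medians, trend = trend,
      insufficient = is.null(trend),
      group_key = group_key, value = value, min_group = min_group
    ),
    class = "mcr_grouped_trend"
  )
}

#' @export
print.mcr_grouped_trend <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf(
      "<mcr_grouped_trend> %s ~ %s: fewer than 2 groups of >= %d mixtures; no trend computed\n",
      x$value, x$group_key, x$min_group
    ))
  } else {
    cat(sprintf(
      "<mcr_grouped_trend> median %s over %s (%d groups): tau = %.4f, p = %.4g\n",
      x$value, x$group_key, nrow(x$medians), x$trend$tau, x$trend$p_value
    ))
  }
  invisible(x)
}

#' Wilcoxon comparison of two sets of values
#'
#' Two-sided Wilcoxon test: unpaired rank-sum by default (the form used for
#' comparing subgroups of unequal size), with a paired option for
#' per-sample comparisons such as case 1 versus case 2 on the same
#' mixtures. Exact for small tie-free samples, normal approximation with
#' tie correction otherwise.
#'
#' @param a,b Numeric vectors (non-empty; equal length when `paired`).
#' @param paired Use the paired signed-rank form.
#' @return A tibble: `statistic`, `p_value`, `n_a`, `n_b`, `paired`.
#' @export
wilcoxon_compare <- function(a, b, paired = FALSE) {
  if (length(a) == 0 || length(b) == 0) {
    abort_domain("Both inputs must be non-empty.")
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = paired))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(a), n_b = length(b), paired = paired
  )
}

#' Default analysis configuration
#'
#' @param top_k,min_detects Data-reduction parameters
#'   ([apply_exclusion_criteria()]).
#' @param nd_cases Non-detect cases to analyse.
#' @param centile_ranges List of `c(low, high)` HI-centile bands.
#' @param hi_threshold HI threshold for the below/above split.
#' @param min_group Minimum group size for grouped medians.
#' @param rank_nd_case Non-detect case used for the mean-HQ ranking.
#' @param top_n_contributors Chemicals shown in the top-contributor table.
#' @return A named list of class `mcr_analysis_config`.
#' @export
analysis_config <- function(top_k = 3, min_detects = 5,
                            nd_cases = c("case1", "case2"),
                            centile_ranges = list(c(49, 51), c(94, 96), c(98, 100)),
                            hi_threshold = 1, min_group = 5,
                            rank_nd_case = "case2", top_n_contributors = 6) {
  structure(
    list(
      top_k = top_k, min_detects = min_detects,
      nd_cases = unique(match_nd_case(nd_cases)),
      centile_ranges = centile_ranges, hi_threshold = hi_threshold,
      min_group = min_group, rank_nd_case = match_nd_case(rank_nd_case),
      top_n_contributors = top_n_contributors
    ),
    class = "mcr_analysis_config"
  )
}

#' Run the full cohort screening analysis
#'
#' Orchestrates the whole pipeline on a measurement table: mean-HQ ranking
#' on the full cohort, data reduction (top-k measurement requirement, then
#' the minimum-detect rule), per-sample screening under each non-detect
#' case, cohort count summaries, the top-contributor table with cumulative
#' shares of the mean HI, the HI threshold split, HI-centile subgroup
#' summaries with between-case Wilcoxon comparisons, and Kendall trend
#' statistics (MCR vs HI, and HI/MCR vs mixture size, both per-mixture and
#' on grouped medians). Deterministic given the cohort and configuration.
#'
#' For trend-versus-size analyses the mixture size is the number of detects
#' under case 1 (non-detects carry no exposure there) and the number of
#' analytes under case 2 (every measured analyte contributes).
#'
#' @inheritParams compute_hq
#' @param config An [analysis_config()].
#' @return An object of class `mcr_analysis`; see [tidy.mcr_analysis()] and
#'   [glance.mcr_analysis()].
#' @export
run_full_analysis <- function(samples, registry,
                              assumptions = exposure_assumptions(),
                              config = analysis_config()) {
  stopifnot(inherits(config, "mcr_analysis_config"))
  samples <- validate_samples(samples)

  ranking_full <- rank_chemicals_by_mean_hq(
    samples, registry, assumptions,
    nd_case = config$rank_nd_case
  )
  exclusion <- apply_exclusion_criteria(
    samples, ranking_full,
    top_k = config$top_k, min_detects = config$min_detects
  )
  retained <- exclusion$retained
  if (nrow(retained) == 0) {
    abort_domain("No samples survive the exclusion criteria.")
  }

  results <- screen_mixtures(retained, registry, assumptions, nd_case = config$nd_cases)

  count_summary <- results |>
    dplyr::filter(.data$nd_case == config$nd_cases[1]) |>
    (\(d) tibble(
      statistic = c("n_detects", "n_nondetects", "n_analytes"),
      minimum = c(
        min(d$n_detects), min(d$n_analytes - d$n_detects), min(d$n_analytes)
      ),
      maximum = c(
        max(d$n_detects), max(d$n_analytes - d$n_detects), max(d$n_analytes)
      ),
      mean = c(
        mean(d$n_detects), mean(d$n_analytes - d$n_detects), mean(d$n_analytes)
      )
    ))()

  # top contributors recomputed on the final retained set
  ranking_final <- rank_chemicals_by_mean_hq(
    retained, registry, assumptions,
    nd_case = config$rank_nd_case
  )
  mean_hi <- results |>
    dplyr::filter(.data$nd_case == config$rank_nd_case) |>
    dplyr::pull(.data$hi) |>
    mean()
  top_tbl <- utils::head(ranking_final, config$top_n_contributors)
  top_contributors <- dplyr::mutate(
    top_tbl,
    cumulative_pct_mean_hi = cumulative_contribution(top_tbl$mean_hq, mean_hi)
  )

  per_case <- purrr::map(setNames(config$nd_cases, config$nd_cases), function(case) {
    res <- dplyr::filter(results, .data$nd_case == case)
    mcr_ok <- res$mcr[!is.na(res$mcr)]
    overall <- tibble(
      n = nrow(res),
      min_hi = min(res$hi), max_hi = max(res$hi), mean_hi = mean(res$hi),
      min_mcr = min(mcr_ok), max_mcr = max(mcr_ok), mean_mcr = mean(mcr_ok),
      n_mcr_undefined = sum(is.na(res$mcr))
    )
    hi_split <- split_by_hi(res, threshold = config$hi_threshold)
    centiles <- purrr::map(config$centile_ranges, function(rg) {
      members <- centile_subgroup(res, rg[1], rg[2])
      dplyr::mutate(
        suppressWarnings(summarize_group(members)),
        centile_low = rg[1], centile_high = rg[2], .before = 1
      )
    }) |> purrr::list_rbind()
    size_key <- if (case == "case1") "n_detects" else "n_analytes"
    trends <- list(
      mcr_vs_hi = kendall_trend(res$hi, res$mcr),
      hi_vs_n = kendall_trend(res[[size_key]], res$hi),
      mcr_vs_n = kendall_trend(res[[size_key]], res$mcr),
      hi_vs_n_grouped = grouped_median_trend(
        res,
        group_key = size_key, value = "hi", min_group = config$min_group
      ),
      mcr_vs_n_grouped = grouped_median_trend(
        res,
        group_key = size_key, value = "mcr", min_group = config$min_group
      )
    )
    list(
      results = res, overall = overall, hi_split = hi_split,
      centiles = centiles, trends = trends, size_key = size_key
    )
  })

  case_comparison <- NULL
  if (all(c("case1", "case2") %in% config$nd_cases)) {
    wide <- results |>
      dplyr::select("sample_id", "nd_case", "hi", "mcr") |>
      tidyr::pivot_wider(names_from = "nd_case", values_from = c("hi", "mcr"))
    cc_mcr <- wide[!is.na(wide$mcr_case1) & !is.na(wide$mcr_case2), , drop = FALSE]
    centile_tests <- purrr::map(config$centile_ranges, function(rg) {
      g1 <- centile_subgroup(per_case$case1$results, rg[1], rg[2])
      g2 <- centile_subgroup(per_case$case2$results, rg[1], rg[2])
      dplyr::mutate(
        wilcoxon_compare(g1$mcr[!is.na(g1$mcr)], g2$mcr[!is.na(g2$mcr)]),
        centile_low = rg[1], centile_high = rg[2], .before = 1
      )
    }) |> purrr::list_rbind()
    case_comparison <- list(
      mean_hi_difference = mean(wide$hi_case2 - wide$hi_case1),
      hi_wilcoxon = wilcoxon_compare(wide$hi_case1, wide$hi_case2),
      mcr_wilcoxon = wilcoxon_compare(cc_mcr$mcr_case1, cc_mcr$mcr_case2),
      centile_wilcoxon = centile_tests
    )
  }

  structure(
    list(
      config = config, assumptions = assumptions,
      ranking = ranking_full, exclusion = exclusion,
      results = results, count_summary = count_summary,
      top_contributors = top_contributors,
      per_case = per_case, case_comparison = case_comparison
    ),
    class = "mcr_analysis"
  )
}

#' @export
print.mcr_analysis <- function(x, ...) {
  cat("== MCR cohort screening analysis ==\n")
  with(x$exclusion$counts, cat(sprintf(
    "Samples: %d in -> %d retained (%d missing top-%d chemicals, %d with < %d detects)\n",
    n_in, n_out, n_removed_top_k, x$config$top_k,
    n_removed_min_detects, x$config$min_detects
  )))
  for (case in names(x$per_case)) {
    o <- x$per_case[[case]]$overall
    ab <- x$per_case[[case]]$hi_split$summary
    cat(sprintf(
      "%s: HI %.3g-%.3g (mean %.3g); MCR %.3g-%.3g (mean %.3g); HI >= %g in %.1f%% of mixtures\n",
      case, o$min_hi, o$max_hi, o$mean_hi, o$min_mcr, o$max_mcr, o$mean_mcr,
      x$config$hi_threshold, ab$pct[ab$side == "above"]
    ))
    tau <- x$per_case[[case]]$trends$mcr_vs_hi
    cat(sprintf("  Kendall tau(HI, MCR) = %.4f (p = %.3g)\n", tau$tau, tau$p_value))
  }
  cat("Top contributors to mean HI:\n")
  tc <- x$top_contributors
  for (i in seq_len(nrow(tc))) {
    cat(sprintf(
      "  %d. %s  mean HQ %.3f  cumulative %.0f%%\n",
      i, tc$chemical[i], tc$mean_hq[i], tc$cumulative_pct_mean_hi[i]
    ))
  }
  invisible(x)
}

#' Tidy and one-line summaries of a cohort analysis
#'
#' `tidy()` returns the per-case HI-centile subgroup summaries as one
#' tibble; `glance()` returns one row per non-detect case with the overall
#' HI/MCR summary, the share of mixtures at or above the HI threshold and
#' the MCR-vs-HI Kendall statistics.
#'
#' @param x An `mcr_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mcr_analysis <- function(x, ...) {
  purrr::imap(x$per_case, function(pc, case) {
    dplyr::mutate(pc$centiles, nd_case = case, .before = 1)
  }) |> purrr::list_rbind()
}

#' @rdname tidy.mcr_analysis
#' @export
glance.mcr_analysis <- function(x, ...) {
  purrr::imap(x$per_case, function(pc, case) {
    ab <- pc$hi_split$summary
    dplyr::mutate(
      pc$overall,
      nd_case = case, .before = 1,
      pct_hi_above = ab$pct[ab$side == "above"],
      tau_mcr_hi = pc$trends$mcr_vs_hi$tau,
      p_mcr_hi = pc$trends$mcr_vs_hi$p_value,
      n_retained = x$exclusion$counts$n_out
    )
  }) |> purrr::list_rbind()
}
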