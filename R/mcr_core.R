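#' Hazard index, maximum hazard quotient and MCR of one mixture
#'
#' Under dose additivity the cumulative exposure of a mixture is the hazard
#' index, HI = sum of the component HQs, and the largest single-chemical
#' contribution is MHQ = max HQ. Their ratio, the maximum cumulative ratio
#' MCR = HI / MHQ, is bounded by 1 and the number of components with a
#' nonzero HQ: values near 1 mean one chemical dominates the mixture's
#' predicted toxicity, larger values mean a chemical-by-chemical assessment
#' would understate the cumulative hazard. A vector of all-zero HQs has
#' HI = 0 and an undefined MCR (returned as `NA` with `mcr_defined =
#' FALSE`).
#'
#' Ties in the maximum do not affect HI or MCR; `top_chemical` reports the
#' lexicographically first tied name (or index when the vector is unnamed).
#'
#' @param hq Non-empty numeric vector of non-negative hazard quotients,
#'   optionally named by chemical.
#' @return A one-row tibble: `hi`, `mhq`, `mcr`, `mcr_defined`,
#'   `n_components`, `n_nonzero`, `top_chemical`.
#' @examples
#' evaluate_mixture(c(a = 0.2, b = 0.2, c = 0.2, d = 0.2, e = 0.2)) # MCR = 5
#' @export
evaluate_mixture <- function(hq) {
  if (length(hq) == 0) {
    abort_domain("`hq` must contain at least one component.")
  }
  check_number(hq, "hq", lower = 0)
  hi <- sum(hq)
  mhq <- max(hq)
  nms <- names(hq) %||% as.character(seq_along(hq))
  if (mhq > 0) {
    top <- sort(nms[hq == mhq])[1]
    mcr <- hi / mhq
  } else {
    top <- NA_character_
    mcr <- NA_real_
  }
  tibble(
    hi = hi, mhq = mhq, mcr = mcr, mcr_defined = mhq > 0,
    n_components = length(hq), n_nonzero = sum(hq > 0), top_chemical = top
  )
}

#' Fraction of the hazard index missed by a single-chemical assessment
#'
#' For a mixture with maximum cumulative ratio `mcr`, assessing only the
#' largest single-chemical HQ captures `1/mcr` of the hazard index;
#' `1 - 1/mcr` is missed. An MCR of 5 means 80% of the HI would be missed,
#' an MCR of 1.25 means 20%.
#'
#' @param mcr Maximum cumulative ratio(s), each `>= 1`.
#' @return Missed fraction in `[0, 1)`.
#' @examples
#' missed_fraction(c(5, 1.25)) # 0.80, 0.20
#' @export
missed_fraction <- function(mcr) {
  if (!is.numeric(mcr) || anyNA(mcr) || any(mcr < 1)) {
    abort_domain("`mcr` must be numeric and >= 1.")
  }
  1 - 1 / mcr
}

#' Screen every mixture in a cohort
#'
#' Computes per-sample hazard quotients (via [compute_hq()]) and collapses
#' them to one row per sample: HI, MHQ, MCR, the chemical attaining the
#' maximum, and the sample's raw analyte/detect counts (counted over all
#' measured analytes, whether or not a permitted dose exists). Samples whose
#' HQ vector is all zero — possible under case 1 when nothing with a PD was
#' detected — carry `mcr = NA` and are excluded from MCR summaries
#' downstream.
#'
#' @inheritParams compute_hq
#' @param nd_case Character vector of non-detect cases to evaluate
#'   (`"case1"`, `"case2"` or both); results are stacked with an `nd_case`
#'   column.
#' @return A tibble of class `mcr_screen` with columns `sample_id`,
#'   `nd_case`, `hi`, `mhq`, `mcr`, `mcr_defined`, `n_detects`,
#'   `n_analytes`, `top_chemical`.
#' @export
screen_mixtures <- function(samples, registry,
                            assumptions = exposure_assumptions(),
                            nd_case = c("case1", "case2")) {
  samples <- validate_samples(samples)
  nd_case <- unique(match_nd_case(nd_case))

  counts <- samples |>
    dplyr::filter(.data$measured) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_detects = sum(.data$detected),
      n_analytes = dplyr::n(),
      .groups = "drop"
    )

  one_case <- function(case) {
    hq_tbl <- compute_hq(samples, registry, assumptions, nd_case = case)
    per_sample <- hq_tbl |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        hi = sum(.data$hq),
        mhq = max(.data$hq),
        top_chemical = sort(.data$analyte[.data$hq == max(.data$hq)])[1],
        .groups = "drop"
      ) |>
      dplyr::mutate(
        mcr_defined = .data$mhq > 0,
        mcr = dplyr::if_else(.data$mcr_defined, .data$hi / .data$mhq, NA_real_),
        top_chemical = dplyr::if_else(.data$mcr_defined, .data$top_chemical, NA_character_)
      )
    # samples with measurements but no PD-resolvable analyte at all
    dplyr::left_join(counts, per_sample, by = "sample_id") |>
      dplyr::mutate(
        hi = dplyr::coalesce(.data$hi, 0),
        mhq = dplyr::coalesce(.data$mhq, 0),
        mcr_defined = dplyr::coalesce(.data$mcr_defined, FALSE),
        nd_case = case
      )
  }

  out <- purrr::map(nd_case, one_case) |>
    purrr::list_rbind() |>
    dplyr::select(
      "sample_id", "nd_case", "hi", "mhq", "mcr", "mcr_defined",
      "n_detects", "n_analytes", "top_chemical"
    )
  class(out) <- c("mcr_screen", class(out))
  out
}

#' Rank chemicals by their mean hazard quotient across a cohort
#'
#' The importance of measuring a chemical is judged by the mean of its HQs
#' over the cohort's mixtures; the ranking determines which chemicals a
#' sample must have been assayed for to be retained (see
#' [apply_exclusion_criteria()]). By default the mean is taken over the
#' samples in which the chemical was measured (a non-detect contributes its
#' imputed HQ), which avoids penalising sparsely assayed chemicals;
#' `over = "all"` divides by the full number of samples instead.
#'
#' @inheritParams compute_hq
#' @param nd_case Non-detect case used for the ranking (`"case2"` by
#'   default, so censored observations still contribute).
#' @param over `"measured"` (default) or `"all"` — the denominator of the
#'   mean.
#' @return A tibble `chemical`, `mean_hq`, `n_samples`, `rank`, sorted by
#'   decreasing mean HQ (ties broken alphabetically for determinism).
#' @export
rank_chemicals_by_mean_hq <- function(samples, registry,
                                      assumptions = exposure_assumptions(),
                                      nd_case = "case2",
                                      over = c("measured", "all")) {
  over <- match.arg(over)
  samples <- validate_samples(samples)
  if (nrow(samples) == 0) {
    abort_domain("Cannot rank chemicals in an empty cohort.")
  }
  hq_tbl <- compute_hq(samples, registry, assumptions, nd_case = nd_case)
  denom_all <- dplyr::n_distinct(samples$sample_id)
  out <- hq_tbl |>
    dplyr::group_by(chemical = .data$analyte) |>
    dplyr::summarise(
      total_hq = sum(.data$hq),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_hq = .data$total_hq / if (over == "all") denom_all else .data$n_samples
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_hq), .data$chemical) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("chemical", "mean_hq", "n_samples", "rank")
  out
}

#' Apply the cohort data-reduction rules
#'
#' Two reduction rules guard against biased MCR estimates: a sample is
#' dropped (i) if any of the `top_k` chemicals with the largest mean HQs was
#' not in its analytical panel — a mixture missing a known major contributor
#' cannot be scored fairly — and (ii) if fewer than `min_detects` of its
#' analytes were detected, since an MCR from very few detected components is
#' unstable. Rules are applied in that order and the log records which rule
#' removed each excluded sample.
#'
#' @inheritParams compute_hq
#' @param ranked_chemicals Ranking tibble from [rank_chemicals_by_mean_hq()]
#'   (or any data frame with `chemical` ordered by importance).
#' @param top_k Number of top-ranked chemicals that must have been measured
#'   (0 disables the rule).
#' @param min_detects Minimum number of detected analytes (0 disables).
#' @return A list of class `mcr_exclusion`: `retained` (the surviving rows
#'   of `samples`), `log` (tibble `sample_id`, `rule`), and `counts`
#'   (samples in, removed per rule, samples out).
#' @export
apply_exclusion_criteria <- function(samples, ranked_chemicals, top_k = 3,
                                     min_detects = 5) {
  samples <- validate_samples(samples)
  check_number(top_k, "top_k", lower = 0)
  check_number(min_detects, "min_detects", lower = 0)
  top <- normalize_chemical(utils::head(ranked_chemicals$chemical, top_k))

  per_sample <- samples |>
    dplyr::filter(.data$measured) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      has_top = length(setdiff(top, normalize_chemical(.data$analyte))) == 0,
      n_detects = sum(.data$detected),
      .groups = "drop"
    )

  drop_top <- per_sample$sample_id[!per_sample$has_top]
  drop_det <- per_sample$sample_id[per_sample$has_top &
    per_sample$n_detects < min_detects]
  log <- dplyr::bind_rows(
    tibble(sample_id = drop_top, rule = "top_k_not_measured"),
    tibble(sample_id = drop_det, rule = "min_detects")
  )
  retained <- dplyr::filter(samples, !.data$sample_id %in% log$sample_id)
  structure(
    list(
      retained = retained,
      log = log,
      counts = tibble(
        n_in = nrow(per_sample),
        n_removed_top_k = length(drop_top),
        n_removed_min_detects = length(drop_det),
        n_out = nrow(per_sample) - nrow(log)
      )
    ),
    class = "mcr_exclusion"
  )
}

#' @export
print.mcr_exclusion <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "<mcr_exclusion> %d samples in -> %d out (%d missing a top-k chemical, %d below the detect minimum)\n",
    n_in, n_out, n_removed_top_k, n_removed_min_detects
  )))
  invisible(x)
}

#' Cumulative contribution of ranked mean HQs to the cohort mean HI
#'
#' Given the mean HQs of the leading chemicals (in decreasing order) and the
#' cohort's total mean HI, returns each chemical's running share of the mean
#' HI in percent — the "top six chemicals contribute X% of the mixtures'
#' HI" style of summary.
#'
#' @param mean_hqs Numeric vector of mean HQs, ordered.
#' @param total_mean_hi Cohort mean HI; must be at least `sum(mean_hqs)` and
#'   positive.
#' @return Numeric vector of cumulative percentages, same length and order
#'   as `mean_hqs`.
#' @export
cumulative_contribution <- function(mean_hqs, total_mean_hi) {
  check_number(mean_hqs, "mean_hqs", lower = 0)
  check_number(total_mean_hi, "total_mean_hi", lower = 0, allow_zero = FALSE)
  if (sum(mean_hqs) > total_mean_hi * (1 + 1e-12)) {
    abort_domain("`total_mean_hi` must be at least the sum of `mean_hqs`.")
  }
  cumsum(mean_hqs) / total_mean_hi * 100
}
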