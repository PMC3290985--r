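screen_results <- function(hi, mcr = NULL, n_detects = NULL, n_analytes = NULL) {
  n <- length(hi)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    nd_case = "case1",
    hi = hi,
    mhq = if (is.null(mcr)) hi else hi / mcr,
    mcr = if (is.null(mcr)) rep(1, n) else mcr,
    mcr_defined = TRUE,
    n_detects = if (is.null(n_detects)) rep(5L, n) else n_detects,
    n_analytes = if (is.null(n_analytes)) rep(10L, n) else n_analytes,
    top_chemical = "x"
  )
}

test_that("centile subgroups follow the rank/N half-open convention", {
  res <- screen_results(hi = seq(0.01, 1, length.out = 100))
  grp <- centile_subgroup(res, 49, 51)
  expect_identical(grp$hi_rank, 50:51)

  expect_identical(nrow(centile_subgroup(res, 0, 100)), 100L)

  # at cohort size 618 the 2-point band holds 12-13 mixtures under this
  # convention; published groups of 11 reflect a different unstated one
  res618 <- screen_results(hi = seq_len(618) / 100)
  expect_true(nrow(centile_subgroup(res618, 49, 51)) %in% 11:13)

  # deterministic under ties: reordering the input changes nothing
  tied <- screen_results(hi = rep(c(1, 2, 3, 3, 3), 4))
  g1 <- centile_subgroup(tied, 40, 60)
  g2 <- centile_subgroup(tied[rev(seq_len(nrow(tied))), ], 40, 60)
  expect_setequal(g1$sample_id, g2$sample_id)

  expect_error(centile_subgroup(res[0, ], 49, 51), class = "mcrscreen_domain_error")
  expect_error(centile_subgroup(res, 51, 49), class = "mcrscreen_domain_error")
})

test_that("subgroup summaries are plain min/max/mean of member MCRs", {
  expect_equal(
    summarize_group(tibble::tibble(mcr = 2.0)),
    tibble::tibble(
      n_members = 1L, min_mcr = 2, max_mcr = 2, mean_mcr = 2, n_undefined = 0L
    )
  )
  s <- summarize_group(tibble::tibble(mcr = c(1, 3)))
  expect_equal(c(s$min_mcr, s$max_mcr, s$mean_mcr), c(1, 3, 2))

  withr::with_seed(99, {
    v <- rlnorm(20, 0.5, 0.4) + 1
    s <- summarize_group(tibble::tibble(mcr = v))
    expect_equal(s$min_mcr, sort(v)[1])
    expect_equal(s$max_mcr, sort(v)[20])
    expect_equal(s$mean_mcr, sum(v) / 20)
    expect_true(s$min_mcr <= s$mean_mcr && s$mean_mcr <= s$max_mcr)
  })

  expect_warning(
    summarize_group(tibble::tibble(mcr = c(2, NA))),
    class = "mcrscreen_undefined_mcr"
  )
  expect_error(summarize_group(tibble::tibble(mcr = numeric())),
    class = "mcrscreen_domain_error"
  )
})

test_that("the HI split sends the threshold itself to the upper side", {
  res <- screen_results(hi = c(0.5, 1.5))
  sp <- split_by_hi(res)
  expect_identical(nrow(sp$below), 1L)
  expect_identical(nrow(sp$above), 1L)
  expect_equal(sp$summary$pct, c(50, 50))

  all_low <- split_by_hi(screen_results(hi = c(0.1, 0.2, 0.3)))
  expect_identical(nrow(all_low$above), 0L)
  expect_equal(all_low$summary$pct[all_low$summary$side == "above"], 0)

  at <- split_by_hi(screen_results(hi = c(0.5, 1.0)))
  expect_identical(at$above$sample_id, "s002")
})

test_that("kendall trend agrees with brute-force pair counting", {
  up <- kendall_trend(1:10, (1:10)^2)
  expect_equal(up$tau, 1)
  down <- kendall_trend(1:10, -(1:10))
  expect_equal(down$tau, -1)

  tied_x <- c(1, 1, 2, 2, 3, 4)
  tied_y <- c(2, 1, 1, 3, 3, 2)
  expect_equal(kendall_trend(tied_x, tied_y)$tau, tau_b_oracle(tied_x, tied_y))

  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(3:8, 1)
      x <- sample(1:4, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(kendall_trend(x, y)$tau, tau_b_oracle(x, y), tolerance = 1e-12)
    }
  })

  expect_error(kendall_trend(1:3, 1:4), class = "mcrscreen_domain_error")
})

test_that("wilcoxon comparison agrees with exhaustive permutation enumeration", {
  same <- wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  shifted <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(shifted$p_value, wilcoxon_exact_oracle(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(shifted$p_value, 0.1)

  withr::with_seed(17, {
    for (i in 1:30) {
      m <- sample(2:4, 1)
      n <- sample(2:4, 1)
      repeat {
        pooled <- round(runif(m + n), 6)
        if (!anyDuplicated(pooled)) break
      }
      a <- pooled[seq_len(m)]
      b <- pooled[-seq_len(m)]
      expect_equal(
        wilcoxon_compare(a, b)$p_value, wilcoxon_exact_oracle(a, b),
        tolerance = 1e-12
      )
    }
    # large shift, large n: far in the tail
    big <- wilcoxon_compare(rnorm(60), rnorm(60) + 3)
    expect_lt(big$p_value, 1e-4)
  })

  expect_error(wilcoxon_compare(numeric(), 1:3), class = "mcrscreen_domain_error")
})

test_that("grouped-median trends drop small groups before testing", {
  res <- screen_results(
    hi = c(rep(1, 4), rep(2, 5), rep(3, 6)),
    n_detects = c(rep(10L, 4), rep(20L, 5), rep(30L, 6))
  )
  gt <- grouped_median_trend(res, "n_detects", "hi", min_group = 5)
  expect_identical(gt$medians$n, c(20L, 30L))
  expect_identical(gt$medians$n_members, c(5L, 6L))

  # hand-built three-group toy: medians and tau by enumeration
  res3 <- screen_results(
    hi = c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14, 6, 7, 8, 9, 6.5),
    n_detects = rep(c(5L, 10L, 15L), each = 5)
  )
  gt3 <- grouped_median_trend(res3, "n_detects", "hi", min_group = 5)
  expect_equal(gt3$medians$median_value, c(3, 12, 7))
  expect_equal(gt3$trend$tau, tau_b_oracle(c(5, 10, 15), c(3, 12, 7)))

  # all-equal medians give tau 0
  flat <- screen_results(
    hi = rep(2, 15), n_detects = rep(c(5L, 10L, 15L), each = 5)
  )
  expect_equal(grouped_median_trend(flat, "n_detects", "hi")$trend$tau, 0)

  # fewer than two surviving groups is an insufficient-data outcome
  tiny <- screen_results(hi = 1:4, n_detects = c(1L, 1L, 2L, 2L))
  out <- grouped_median_trend(tiny, "n_detects", "hi", min_group = 5)
  expect_true(out$insufficient)
  expect_null(out$trend)
})

test_that("the full analysis is deterministic and internally consistent", {
  cfg <- groundwater_config(n_samples = 120, seed = 3)
  cohort <- simulate_cohort(cfg)
  reg <- config_pd_registry(cfg)
  a1 <- run_full_analysis(cohort, reg)
  a2 <- run_full_analysis(cohort, reg)
  expect_equal(a1$results, a2$results)
  expect_equal(tidy(a1), tidy(a2))

  # report agrees with direct module calls
  ranked <- rank_chemicals_by_mean_hq(cohort, reg)
  excl <- apply_exclusion_criteria(cohort, ranked, top_k = 3, min_detects = 5)
  expect_equal(a1$exclusion$counts, excl$counts)
  res2 <- screen_mixtures(excl$retained, reg, nd_case = "case2")
  expect_equal(
    dplyr::filter(a1$results, nd_case == "case2")$hi,
    res2$hi[match(
      dplyr::filter(a1$results, nd_case == "case2")$sample_id,
      res2$sample_id
    )]
  )
  gl <- glance(a1)
  expect_identical(nrow(gl), 2L)
  expect_true(all(gl$min_mcr >= 1))

  # case2 HI dominates case1 per sample; the mean difference is positive
  wide <- tidyr::pivot_wider(
    dplyr::select(a1$results, sample_id, nd_case, hi),
    names_from = nd_case, values_from = hi
  )
  expect_true(all(wide$case2 >= wide$case1))
  expect_gt(a1$case_comparison$mean_hi_difference, 0)
})

test_that("a cohort of identical mixtures yields identical subgroup statistics", {
  reg <- toy_registry()
  one <- function(sid) {
    dplyr::bind_rows(
      measurement(sid, "Arsenic", detected = TRUE, conc = 0.003),
      measurement(sid, "Boron", detected = TRUE, conc = 0.3)
    )
  }
  cohort <- purrr::map(sprintf("s%02d", 1:20), one) |> purrr::list_rbind()
  res <- screen_mixtures(cohort, reg, nd_case = "case1")
  expect_equal(length(unique(res$mcr)), 1L)
  grp <- summarize_group(centile_subgroup(res, 49, 51))
  expect_equal(grp$min_mcr, grp$max_mcr)
  expect_equal(grp$mean_mcr, res$mcr[1])
})

test_that("dominance-tuned cohorts show MCR declining with HI in both cases", {
  cfg <- groundwater_config(n_samples = 250, seed = 21)
  cohort <- simulate_cohort(cfg)
  reg <- config_pd_registry(cfg)
  a <- run_full_analysis(cohort, reg)
  for (case in c("case1", "case2")) {
    tr <- a$per_case[[case]]$trends$mcr_vs_hi
    expect_lt(tr$tau, 0)
    expect_lt(tr$p_value, 0.01)
  }
  # subgroup mean MCR declines from typical to upper-bound HI bands
  td <- tidy(a)
  for (case in c("case1", "case2")) {
    m <- td$mean_mcr[td$nd_case == case]
    expect_gte(m[1], m[2])
    expect_gte(m[2], m[3])
  }
})
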