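test_that("mixture evaluation reproduces sum/max/ratio structure", {
  one <- evaluate_mixture(c(x = 0.5))
  expect_equal(one$hi, 0.5)
  expect_equal(one$mcr, 1.0)

  equal5 <- evaluate_mixture(rep(0.2, 5))
  expect_equal(equal5$hi, 1.0)
  expect_equal(equal5$mcr, 5.0)

  # printed mean-HQ vector of the six dominant ground-water contributors
  v <- c(0.362, 0.217, 0.098, 0.059, 0.040, 0.040)
  res <- evaluate_mixture(v)
  expect_equal(res$hi, 0.816)
  expect_equal(res$mcr, 2.2541, tolerance = 1e-3 / 2.2541)

  zero <- evaluate_mixture(c(a = 0, b = 0))
  expect_equal(zero$hi, 0)
  expect_false(zero$mcr_defined)
  expect_true(is.na(zero$mcr))

  expect_error(evaluate_mixture(numeric()), class = "mcrscreen_domain_error")
  expect_error(evaluate_mixture(c(0.1, -0.2)), class = "mcrscreen_domain_error")
})

test_that("ties in the maximum report the first name alphabetically", {
  res <- evaluate_mixture(c(zeta = 0.3, alpha = 0.3, mid = 0.1))
  expect_identical(res$top_chemical, "alpha")
  expect_equal(res$mcr, 0.7 / 0.3)
})

test_that("MCR is bounded by 1 and the nonzero component count", {
  withr::with_seed(123, {
    for (i in 1:500) {
      n <- sample(1:30, 1)
      hq <- rlnorm(n, meanlog = -3, sdlog = 2)
      res <- evaluate_mixture(hq)
      expect_gte(res$mcr, 1)
      expect_lte(res$mcr, res$n_nonzero)
      # independent recomputation
      expect_equal(res$hi, sum(hq), tolerance = 1e-12)
      expect_equal(res$mcr, sum(hq) / max(hq), tolerance = 1e-12)
    }
  })
})

test_that("missed fraction is the complement of the captured share", {
  expect_equal(missed_fraction(5), 0.80)
  expect_equal(missed_fraction(1.25), 0.20)
  expect_equal(missed_fraction(1), 0)
  expect_error(missed_fraction(0.99), class = "mcrscreen_domain_error")
  # strictly increasing, bounded by 1
  grid <- seq(1, 50, by = 0.25)
  mf <- missed_fraction(grid)
  expect_true(all(diff(mf) > 0))
  expect_true(all(mf < 1))
})

test_that("chemical ranking averages HQs over the samples measured", {
  reg <- toy_registry()
  # Arsenic HQ: s1 -> 0.009*2/60/3e-4 = 1; s2 not measured.
  # Boron HQ: s1 -> 0.03*2/60/0.2 = 0.005; s2 -> 0.3*2/60/0.2 = 0.05.
  cohort <- dplyr::bind_rows(
    measurement("s1", "Arsenic", detected = TRUE, conc = 0.009),
    measurement("s1", "Boron", detected = TRUE, conc = 0.03),
    measurement("s2", "Boron", detected = TRUE, conc = 0.3)
  )
  rk <- rank_chemicals_by_mean_hq(cohort, reg)
  expect_identical(rk$chemical, c("Arsenic", "Boron"))
  expect_equal(rk$mean_hq, c(1, mean(c(0.005, 0.05))))

  rk_all <- rank_chemicals_by_mean_hq(cohort, reg, over = "all")
  expect_equal(rk_all$mean_hq[rk_all$chemical == "Arsenic"], 0.5)

  # a chemical that alone carries nonzero HQ ranks first
  only_a <- dplyr::bind_rows(
    measurement("s1", "Arsenic", detected = TRUE, conc = 0.001),
    measurement("s1", "Boron", detected = FALSE, dl = 0.01),
    measurement("s2", "Arsenic", detected = TRUE, conc = 0.002)
  )
  expect_identical(
    rank_chemicals_by_mean_hq(only_a, reg, nd_case = "case1")$chemical[1],
    "Arsenic"
  )
})

test_that("exclusion rules drop unmeasured-top-k and detect-poor samples", {
  reg <- toy_registry()
  ranked <- tibble::tibble(chemical = c("Arsenic", "Boron"))
  cohort <- dplyr::bind_rows(
    measurement("s1", "Arsenic", detected = TRUE, conc = 0.001),
    measurement("s1", "Boron", detected = TRUE, conc = 0.01),
    measurement("s2", "Boron", detected = TRUE, conc = 0.01), # Arsenic missing
    measurement("s3", "Arsenic", detected = TRUE, conc = 0.001),
    measurement("s3", "Boron", detected = FALSE, dl = 0.01)
  )
  excl <- apply_exclusion_criteria(cohort, ranked, top_k = 2, min_detects = 0)
  expect_setequal(unique(excl$retained$sample_id), c("s1", "s3"))
  expect_identical(excl$log$rule[excl$log$sample_id == "s2"], "top_k_not_measured")

  # minimum-detect rule: 4 detects is not enough when 5 are required
  four <- purrr::map(
    1:4, ~ measurement("s4", paste0("chem", .x), detected = TRUE, conc = 1)
  ) |> purrr::list_rbind()
  excl2 <- apply_exclusion_criteria(four, ranked[0, ], top_k = 0, min_detects = 5)
  expect_identical(nrow(excl2$retained), 0L)
  expect_identical(excl2$log$rule, "min_detects")

  # disabled rules leave the cohort untouched
  excl3 <- apply_exclusion_criteria(cohort, ranked, top_k = 0, min_detects = 0)
  expect_identical(excl3$retained, cohort)
  expect_identical(nrow(excl3$log), 0L)
})

test_that("requiring the top six retains a subset of requiring the top three", {
  cfg <- groundwater_config(n_samples = 150, seed = 11)
  cohort <- simulate_cohort(cfg)
  reg <- config_pd_registry(cfg)
  ranked <- rank_chemicals_by_mean_hq(cohort, reg)
  top3 <- apply_exclusion_criteria(cohort, ranked, top_k = 3, min_detects = 5)
  top6 <- apply_exclusion_criteria(cohort, ranked, top_k = 6, min_detects = 5)
  ids3 <- unique(top3$retained$sample_id)
  ids6 <- unique(top6$retained$sample_id)
  expect_true(all(ids6 %in% ids3))
  expect_lte(length(ids6), length(ids3))
})

test_that("cumulative contributions accumulate to the expected share", {
  v <- c(0.362, 0.217, 0.098, 0.059, 0.040, 0.040)
  # denominator back-solved from the leading chemical's 33% share
  cum <- cumulative_contribution(v, 1.097)
  expect_equal(cum[1], 33, tolerance = 1 / 33)
  expect_equal(cum[6], 74, tolerance = 1 / 74)
  expect_true(all(diff(cum) >= 0))

  expect_equal(cumulative_contribution(2, 2), 100)
  expect_equal(cumulative_contribution(c(0, 0, 0), 5), c(0, 0, 0))
  expect_error(cumulative_contribution(c(3, 3), 5), class = "mcrscreen_domain_error")
})

test_that("cohort screening matches per-sample recomputation", {
  cfg <- groundwater_config(n_samples = 40, seed = 5)
  cohort <- simulate_cohort(cfg)
  reg <- config_pd_registry(cfg)
  res <- screen_mixtures(cohort, reg, nd_case = "case2")
  expect_s3_class(res, "mcr_screen")
  expect_identical(nrow(res), dplyr::n_distinct(cohort$sample_id))

  hq <- compute_hq(cohort, reg, nd_case = "case2")
  for (sid in head(res$sample_id, 5)) {
    v <- hq$hq[hq$sample_id == sid]
    row <- res[res$sample_id == sid, ]
    expect_equal(row$hi, sum(v), tolerance = 1e-12)
    expect_equal(row$mcr, sum(v) / max(v), tolerance = 1e-12)
  }
  # raw panel counts, independent of PD availability
  counts <- dplyr::count(dplyr::filter(cohort, measured), sample_id)
  expect_equal(
    res$n_analytes[match(counts$sample_id, res$sample_id)],
    counts$n
  )
})
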