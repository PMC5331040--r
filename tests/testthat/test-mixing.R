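test_that("the mixing fraction maps endmembers and midpoint exactly", {
  pair <- study_pair()
  expect_equal(mixing_fraction(-29.3, pair)$raw_fraction, 0)
  expect_equal(mixing_fraction(-13.3, pair)$raw_fraction, 1)
  expect_equal(mixing_fraction(-21.3, pair)$raw_fraction, 0.5)
  expect_equal(mixing_fraction(-19.7, pair)$raw_fraction, 0.6)
  expect_identical(mixing_fraction(-21.3, pair)$flag, "in_range")
})

test_that("out-of-range raw fractions are clamped with the right flag", {
  pair <- study_pair()
  high <- mixing_fraction(-12.0, pair)
  expect_equal(high$raw_fraction, 1.08125)
  expect_equal(high$fraction, 1)
  expect_identical(high$flag, "clamped_high")
  low <- mixing_fraction(-30.1, pair)
  expect_lt(low$raw_fraction, 0)
  expect_equal(low$fraction, 0)
  expect_identical(low$flag, "clamped_low")
  # fraction and the implied EOM fraction sum to 1 exactly
  expect_equal(high$fraction + (1 - high$fraction), 1)
})

test_that("the mixing fraction is affine-invariant, linear and monotone", {
  pair <- study_pair()
  for (seed in 1:10) {
    delta <- withr::with_seed(seed, runif(5, -29, -14))
    c0 <- withr::with_seed(seed + 50, runif(1, -3, 3))
    shifted_pair <- endmember_pair(
      endmember_estimate(-13.3 + c0, 0, 7, "root"),
      endmember_estimate(-29.3 + c0, 0, 12, "eom")
    )
    expect_equal(
      mixing_fraction(delta + c0, shifted_pair)$raw_fraction,
      mixing_fraction(delta, pair)$raw_fraction
    )
    # linearity in delta_s
    a <- withr::with_seed(seed + 100, runif(1))
    mix <- a * delta[1] + (1 - a) * delta[2]
    expect_equal(
      mixing_fraction(mix, pair)$raw_fraction,
      a * mixing_fraction(delta[1], pair)$raw_fraction +
        (1 - a) * mixing_fraction(delta[2], pair)$raw_fraction
    )
    # strictly increasing in delta_s
    sorted <- sort(delta)
    expect_true(all(diff(mixing_fraction(sorted, pair)$raw_fraction) > 0))
  }
})

test_that("the analytic SE matches hand-computed propagation cases", {
  pair <- study_pair() # sds 0
  expect_equal(analytic_se(-21.3, pair, sigma_s = 0.2), 0.2 / 16)
  expect_equal(analytic_se(-21.3, pair, sigma_s = 0), 0)
  # only root-endmember uncertainty, evaluated at the root endmember:
  # SE = sigma_RB * (delta_s - eom) / Delta^2 = sigma_RB / Delta
  pair_rb <- endmember_pair(
    endmember_estimate(-13.3, 0.5, 7, "root"),
    endmember_estimate(-29.3, 0, 12, "eom")
  )
  expect_equal(analytic_se(-13.3, pair_rb, sigma_s = 0), 0.5 / 16)
  expect_error(analytic_se(-21.3, pair, sigma_s = -1), class = "rootmix_numeric_error")
})

test_that("Monte-Carlo uncertainty degenerates to the point estimate without noise", {
  pair <- study_pair()
  mc <- mc_uncertainty(-21.3, pair, sigma_s = 0, draws = 1000, seed = 1)
  expect_equal(mc$ci_low, 0.5)
  expect_equal(mc$ci_high, 0.5)
  expect_equal(mc$se_mc, 0)
  expect_equal(mc$n_rejected, 0L)
})

test_that("Monte-Carlo uncertainty is deterministic given the seed", {
  pair <- study_pair(root_sd = 0.5, eom_sd = 0.3)
  a <- mc_uncertainty(-21.3, pair, draws = 2000, seed = 42)
  b <- mc_uncertainty(-21.3, pair, draws = 2000, seed = 42)
  expect_identical(a, b)
  expect_error(mc_uncertainty(-21.3, pair, draws = 10), class = "rootmix_numeric_error")
})

test_that("Monte-Carlo SE agrees with the analytic SE in the linear regime", {
  pair <- study_pair(root_sd = 0.5, eom_sd = 0.3)
  for (delta in c(-23.3, -21.3, -19.3)) {
    mc <- mc_uncertainty(delta, pair, sigma_s = 0.2, draws = 1e5, seed = 7)
    expect_lt(abs(mc$se_mc / analytic_se(delta, pair, 0.2) - 1), 0.05)
  }
})

test_that("size-class pooling is a mass-weighted mean with the right limits", {
  expect_equal(pool_size_classes(0.6, 0.6, 2, 5), 0.6)
  expect_equal(pool_size_classes(0.9, 0.3, 1, 2), 0.5) # (0.9 + 0.6) / 3
  expect_equal(pool_size_classes(0.8, 0.2, 1, 0), 0.8) # single-class limit
  # carbon concentrations refine the weights when both are present
  expect_equal(
    pool_size_classes(0.9, 0.3, 1, 1, c_conc_coarse = 0.5, c_conc_fine = 0.25),
    (0.5 * 0.9 + 0.25 * 0.3) / 0.75
  )
  expect_error(pool_size_classes(0.5, 0.5, 0, 0), class = "rootmix_numeric_error")
  # pooled fraction bounded by its components
  for (seed in 1:20) {
    x <- withr::with_seed(seed, runif(4))
    pooled <- pool_size_classes(x[1], x[2], x[3] + 0.01, x[4] + 0.01)
    expect_gte(pooled, min(x[1], x[2]))
    expect_lte(pooled, max(x[1], x[2]))
  }
})

test_that("run_mixing yields one result per sample plus pooled records", {
  study <- simulate_study(
    scenario(n_missing = 0L, seed = 8), # complete design: 144 measured
    seed = 8
  )
  results <- run_mixing(study$samples, study_pair(0.5, 0.3))
  expect_equal(sum(results$source == "measured"), 144)
  expect_equal(sum(results$source == "pooled"), 36) # 12 plots x 3 depths
  pooled <- results[results$source == "pooled", ]
  expect_true(all(pooled$size_class == "pooled"))
  expect_true(all(pooled$method == "puerckhauer"))
  expect_true(all(pooled$fraction >= 0 & pooled$fraction <= 1))
  expect_true(all(results$ci_low <= results$ci_high))
})

test_that("pooled fractions equal the mass-weighted mean of their components", {
  fit <- baseline_fit()$fit
  res <- fit$results
  pooled <- res[res$source == "pooled", ]
  for (i in head(seq_len(nrow(pooled)), 5)) {
    cell <- res[res$source == "measured" &
      res$plot_id == pooled$plot_id[i] &
      res$depth == pooled$depth[i] &
      res$method == "puerckhauer", ]
    expect_equal(
      pooled$fraction[i],
      pool_size_classes(
        cell$fraction[cell$size_class == "coarse"],
        cell$fraction[cell$size_class == "fine"],
        cell$dry_mass[cell$size_class == "coarse"],
        cell$dry_mass[cell$size_class == "fine"]
      )
    )
  }
})

test_that("cells lacking a dry mass are skipped with a warning", {
  study <- simulate_study(scenario(n_missing = 0L, seed = 12), seed = 12)
  samples <- study$samples
  samples$dry_mass[samples$method == "puerckhauer" &
    samples$size_class == "fine" &
    samples$plot_id == "P01" & samples$depth == "D1"] <- NA
  expect_warning(
    results <- run_mixing(samples, study_pair(0.5, 0.3)),
    "dry mass missing"
  )
  expect_equal(sum(results$source == "pooled"), 35)
})

test_that("a single sample at the EOM endmember maps to fraction zero", {
  tbl <- read_samples(tiny_samples_csv(delta = c(-29.3, -24.0, -15.0)))
  results <- run_mixing(tbl[1, ], study_pair())
  expect_equal(nrow(results), 1)
  expect_equal(results$fraction, 0)
})
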