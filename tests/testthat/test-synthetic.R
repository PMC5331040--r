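test_that("the factorial design has the documented structure", {
  design <- build_design()
  expect_equal(nrow(design), 144)
  expect_equal(sum(design$method == "humax"), 72)
  expect_equal(sum(design$method == "puerckhauer"), 72)
  expect_equal(dplyr::n_distinct(design$plot_id), 12)
  expect_equal(anyDuplicated(
    design[, c("plot_id", "depth", "method", "position", "size_class")]
  ), 0)
  expect_equal(anyDuplicated(design$sample_id), 0)
  # block and treatment constant within plots, 4 plots per treatment
  per_plot <- unique(design[, c("plot_id", "treatment", "block")])
  expect_equal(nrow(per_plot), 12)
  expect_equal(as.vector(table(per_plot$treatment)), rep(4L, 3))
  expect_equal(nrow(validate_table(
    synthesize_delta13c(
      draw_true_fractions(design, dok2013_scenario(), seed = 1),
      dok2013_scenario(),
      seed = 2
    )
  )), 0)
})

test_that("true fractions follow the scenario's logit model", {
  design <- build_design()
  # no effects, no dispersion: every true fraction equals the baseline
  flat <- scenario(baseline_fraction = 0.6, dispersion_logit = 0)
  t1 <- draw_true_fractions(design, flat, seed = 1)
  expect_equal(t1$true_fraction, rep(0.6, 144))
  # deterministic given seed
  sc <- dok2013_scenario()
  expect_equal(
    draw_true_fractions(design, sc, seed = 9)$true_fraction,
    draw_true_fractions(design, sc, seed = 9)$true_fraction
  )
  expect_true(all(t1$true_fraction > 0 & t1$true_fraction < 1))
  # noiseless cell means increase monotonically with depth
  sc0 <- dok2013_scenario(dispersion_logit = 0.9)
  sc0$dispersion_logit <- 0 # keep calibrated offsets, remove noise
  td <- draw_true_fractions(design, sc0, seed = 1)
  by_depth <- tapply(td$true_fraction, td$depth, mean)
  expect_true(all(diff(by_depth[c("D1", "D2", "D3")]) > 0))
})

test_that("synthesized delta13c inverts the mixing model when noise is zero", {
  design <- build_design()
  sc <- scenario(
    baseline_fraction = 0.5, dispersion_logit = 0,
    root_endmember = c(-13.3, 0), eom_endmember = c(-29.3, 0),
    sigma_instrument = 0
  )
  tbl <- synthesize_delta13c(draw_true_fractions(design, sc, seed = 1), sc, seed = 2)
  expect_equal(tbl$delta13c, rep(-21.3, 144)) # midpoint at f = 0.5
  # pure root with zero SDs sits at the root endmember
  pure <- draw_true_fractions(design, sc, seed = 1)
  pure$true_fraction <- 1
  expect_equal(
    synthesize_delta13c(pure, sc, seed = 3)$delta13c,
    rep(-13.3, 144)
  )
})

test_that("with all noise off, estimated fractions equal true fractions", {
  design <- build_design()
  sc <- dok2013_scenario()
  sc$root_endmember[] <- c(-13.3, 0)
  sc$eom_endmember[] <- c(-29.3, 0)
  sc$sigma_instrument <- 0
  truths <- draw_true_fractions(design, sc, seed = 21)
  tbl <- synthesize_delta13c(truths, sc, seed = 22)
  results <- run_mixing(tbl, study_pair(), sigma_s = 0)
  measured <- results[results$source == "measured", ]
  expect_equal(measured$fraction, truths$true_fraction, tolerance = 1e-12)
})

test_that("missingness removal is bounded, schema-preserving and seeded", {
  study_full <- synthesize_delta13c(
    draw_true_fractions(build_design(), dok2013_scenario(), seed = 4),
    dok2013_scenario(),
    seed = 5
  )
  expect_identical(apply_missingness(study_full, 0, seed = 1), study_full)
  m5 <- apply_missingness(study_full, 5, seed = 1)
  expect_equal(nrow(m5), 139)
  expect_equal(nrow(validate_table(m5)), 0)
  expect_identical(m5, apply_missingness(study_full, 5, seed = 1))
  expect_error(apply_missingness(study_full, 144, seed = 1),
    class = "rootmix_numeric_error"
  )
})

test_that("the reference ley table recovers the EOM endmember", {
  sc <- dok2013_scenario()
  ref0 <- generate_reference_ley(scenario(eom_endmember = c(-29.3, 0)), seed = 2)
  expect_equal(ref0$delta13c, rep(-29.3, 12))
  ref <- generate_reference_ley(sc, n = 12, seed = 6)
  expect_equal(nrow(ref), 12)
  est <- estimate_eom_endmember(ref$delta13c)
  expect_lt(abs(est$mean - -29.3), 3 * 0.3 / sqrt(12)) # CLT bound
  expect_error(generate_reference_ley(sc, n = 1), class = "rootmix_numeric_error")
})

test_that("simulate_study assembles a valid, reproducible study", {
  sc <- dok2013_scenario()
  s1 <- simulate_study(sc, seed = 31)
  s2 <- simulate_study(sc, seed = 31)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$reference, s2$reference)
  expect_equal(nrow(s1$samples), 139)
  expect_equal(nrow(validate_table(s1$samples)), 0)
  expect_equal(nrow(s1$truth), 139)
  expect_identical(s1$truth$sample_id, s1$samples$sample_id)
})

test_that("scenario files round-trip through flat key-value text", {
  sc <- dok2013_scenario(seed = 77)
  path <- tempfile(fileext = ".yml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$effects, sc$effects, tolerance = 1e-6)
  expect_equal(back$baseline_fraction, sc$baseline_fraction)
  expect_equal(back$mass_ratio_fine_to_coarse, sc$mass_ratio_fine_to_coarse)
  expect_equal(back$seed, 77L)
  # the packaged baseline scenario parses and matches the constructor
  packaged <- system.file("extdata", "dok2013_scenario.yml", package = "rootmix")
  expect_true(nzchar(packaged))
  expect_equal(read_scenario(packaged)$effects, dok2013_scenario()$effects,
    tolerance = 1e-6
  )
})

test_that("scenario validation rejects impossible parameters", {
  expect_error(scenario(baseline_fraction = 1.2), class = "rootmix_numeric_error")
  expect_error(scenario(dispersion_logit = -1), class = "rootmix_numeric_error")
  expect_error(
    scenario(root_endmember = c(-29.3, 0.5), eom_endmember = c(-13.3, 0.3)),
    class = "rootmix_numeric_error"
  )
  expect_error(scenario(n_missing = 144), class = "rootmix_numeric_error")
  expect_error(
    scenario(effects = list(bogus = c(x = 1))),
    class = "rootmix_schema_error"
  )
  expect_error(
    scenario(effects = list(depth = c(D9 = 1))),
    class = "rootmix_schema_error"
  )
})
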