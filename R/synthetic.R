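#' Construct a synthetic-study scenario
#'
#' A scenario bundles every generative parameter of a synthetic study: the
#' two endmember distributions, the instrument precision, the baseline
#' recent-root C fraction, per-level factor effects on the logit scale, the
#' per-sample logit-normal dispersion, the number of missing observations,
#' and the fine-to-coarse dry-mass ratio used for size-class pooling.
#'
#' True fractions are generated as
#' `logit(f) = logit(baseline) + sum(effect offsets) + Normal(0, dispersion)`,
#' which keeps fractions strictly inside (0, 1) and yields the long lower
#' tail seen in contaminated field samples.
#'
#' @param baseline_fraction Baseline recent-root C fraction in (0, 1).
#' @param effects Named list of named numeric vectors: logit-scale offsets
#'   for `treatment`, `depth`, `position`, `size_class`, `exclusion` (levels
#'   `no`/`yes`). Missing entries default to zero offsets.
#' @param dispersion_logit SD of per-sample logit-normal noise (default 0.9).
#' @param root_endmember,eom_endmember Numeric `c(mean, sd)` in per mil.
#' @param sigma_instrument Analytical precision of the delta-13C measurement
#'   in per mil (default 0.2).
#' @param n_missing Number of observations removed at random (default 5).
#' @param mass_ratio_fine_to_coarse Fine : coarse dry-mass ratio for
#'   Puerckhauer samples (default 1.82).
#' @param seed Default integer seed for [simulate_study()].
#' @return An object of class `rootmix_scenario` (a named list).
#' @seealso [dok2013_scenario()], [null_scenario()], [simulate_study()]
#' @export
scenario <- function(baseline_fraction = 0.5,
                     effects = list(),
                     dispersion_logit = 0.9,
                     root_endmember = c(mean = -13.3, sd = 0.5),
                     eom_endmember = c(mean = -29.3, sd = 0.3),
                     sigma_instrument = 0.2,
                     n_missing = 5L,
                     mass_ratio_fine_to_coarse = 1.82,
                     seed = 1L) {
  full_effects <- list(
    treatment = zero_offsets(rootmix_treatments),
    depth = zero_offsets(rootmix_depths),
    position = zero_offsets(rootmix_positions),
    size_class = zero_offsets(rootmix_size_classes),
    exclusion = zero_offsets(c("no", "yes"))
  )
  for (nm in names(effects)) {
    if (!nm %in% names(full_effects)) {
      abort_schema(sprintf("unknown effect factor '%s'", nm))
    }
    lv <- names(effects[[nm]])
    bad <- setdiff(lv, names(full_effects[[nm]]))
    if (length(bad) > 0) {
      abort_schema(sprintf(
        "unknown level(s) for effect '%s': %s", nm, paste(bad, collapse = ", ")
      ))
    }
    full_effects[[nm]][lv] <- effects[[nm]][lv]
  }
  sc <- structure(
    list(
      baseline_fraction = baseline_fraction,
      effects = full_effects,
      dispersion_logit = dispersion_logit,
      root_endmember = c(mean = unname(root_endmember[1]), sd = unname(root_endmember[2])),
      eom_endmember = c(mean = unname(eom_endmember[1]), sd = unname(eom_endmember[2])),
      sigma_instrument = sigma_instrument,
      n_missing = as.integer(n_missing),
      mass_ratio_fine_to_coarse = mass_ratio_fine_to_coarse,
      seed = as.integer(seed)
    ),
    class = "rootmix_scenario"
  )
  validate_scenario(sc)
  sc
}

zero_offsets <- function(levels) {
  stats::setNames(rep(0, length(levels)), levels)
}

validate_scenario <- function(sc) {
  if (!(sc$baseline_fraction > 0 && sc$baseline_fraction < 1)) {
    abort_numeric("baseline_fraction must lie strictly in (0, 1)")
  }
  sds <- c(
    sc$dispersion_logit, sc$root_endmember["sd"], sc$eom_endmember["sd"],
    sc$sigma_instrument
  )
  if (any(sds < 0)) abort_numeric("all scenario SDs must be non-negative")
  if (sc$root_endmember["mean"] <= sc$eom_endmember["mean"]) {
    abort_numeric("root endmember must be heavier (larger) than the EOM endmember")
  }
  if (sc$n_missing < 0 || sc$n_missing >= 144) {
    abort_numeric("n_missing must be in [0, design size)")
  }
  if (sc$mass_ratio_fine_to_coarse <= 0) {
    abort_numeric("mass_ratio_fine_to_coarse must be positive")
  }
  # every design cell's noiseless mean must stay inside (0, 1); guaranteed by
  # the logistic link for finite offsets
  offsets <- unlist(sc$effects)
  if (any(!is.finite(offsets))) abort_numeric("effect offsets must be finite")
  invisible(sc)
}

#' @export
print.rootmix_scenario <- function(x, ...) {
  cat(sprintf(
    "<rootmix scenario> baseline %.2f, dispersion %.2f (logit), instrument SD %.2f per mil\n",
    x$baseline_fraction, x$dispersion_logit, x$sigma_instrument
  ))
  cat(sprintf(
    "  endmembers: root %.1f +/- %.1f | eom %.1f +/- %.1f per mil; %d missing; fine:coarse mass %.2f\n",
    x$root_endmember["mean"], x$root_endmember["sd"],
    x$eom_endmember["mean"], x$eom_endmember["sd"],
    x$n_missing, x$mass_ratio_fine_to_coarse
  ))
  invisible(x)
}

# Mean of a logit-normal distribution: E[plogis(N(mu, sigma^2))].
logit_normal_mean <- function(mu, sigma) {
  if (sigma == 0) {
    return(plogis(mu))
  }
  stats::integrate(
    function(z) plogis(mu + sigma * z) * dnorm(z),
    -Inf, Inf, rel.tol = 1e-9
  )$value
}

# Logit offset whose logit-normal mean equals `target` at dispersion `sigma`.
logit_offset_for_mean <- function(target, sigma) {
  stats::uniroot(
    function(mu) logit_normal_mean(mu, sigma) - target,
    interval = c(-15, 15), tol = 1e-9
  )$root
}

#' The DOK-2013 baseline scenario
#'
#' Scenario whose generative parameters emulate the 2013 maize root sampling
#' on the Swiss DOK long-term trial: endmembers -13.3 +/- 0.5 per mil (root)
#' and -29.3 +/- 0.3 per mil (EOM), instrument SD 0.2 per mil, 5 of 144
#' observations missing, and logit-scale factor effects calibrated so that
#' the noiseless group means reproduce the reported group means of the
#' recent-root C fraction: 55/59/66% across treatments, 52/60/68% across
#' depths, 73/52% within vs between rows, 73/42% for coarse vs fine size
#' classes, and 74% vs 53% with and without EOM exclusion. The calibration
#' inverts the logit-normal mean function at the scenario's dispersion, so
#' the stated percentages are the actual expected group means under noise.
#' The fine-to-coarse mass ratio (1.82) is chosen so that mass-weighted
#' pooling of the coarse (73%) and fine (42%) means reproduces the 53%
#' unexcluded pooled mean.
#'
#' @param dispersion_logit Per-sample logit-scale SD (default 0.9).
#' @param seed Default seed stored in the scenario.
#' @return A `rootmix_scenario`.
#' @export
dok2013_scenario <- function(dispersion_logit = 0.9, seed = 1L) {
  inv <- function(m) logit_offset_for_mean(m, dispersion_logit)
  base <- 0.5 # logit 0; group contrasts are carried entirely by the offsets
  mu_hum_row <- inv(0.73) # humax row = exclusion effect alone
  mu_hum_inter <- inv(0.52)
  scenario(
    baseline_fraction = base,
    effects = list(
      treatment = c(
        BIOORG1 = inv(0.55) - inv(0.60),
        BIOORG2 = inv(0.59) - inv(0.60),
        CONFYM2 = inv(0.66) - inv(0.60)
      ),
      depth = c(
        D1 = inv(0.52) - inv(0.60),
        D2 = 0,
        D3 = inv(0.68) - inv(0.60)
      ),
      position = c(row = 0, inter_row = mu_hum_inter - mu_hum_row),
      size_class = c(pooled = 0, coarse = inv(0.73), fine = inv(0.42)),
      exclusion = c(no = 0, yes = mu_hum_row)
    ),
    dispersion_logit = dispersion_logit,
    n_missing = 5L,
    mass_ratio_fine_to_coarse = 1.82,
    seed = seed
  )
}

#' A no-effect scenario for calibration studies
#'
#' Identical nuisance structure to [dok2013_scenario()] (endmembers,
#' dispersion, instrument noise, missingness) but with every factor effect
#' set to zero -- the null under which permutation-test type-I error is
#' assessed.
#'
#' @inheritParams dok2013_scenario
#' @return A `rootmix_scenario`.
#' @export
null_scenario <- function(dispersion_logit = 0.9, seed = 1L) {
  scenario(
    baseline_fraction = 0.5,
    effects = list(),
    dispersion_logit = dispersion_logit,
    n_missing = 5L,
    seed = seed
  )
}

#' Build the complete factorial sampling design
#'
#' Three treatments x four field blocks give 12 plots. Per plot and depth
#' layer (D1-D3) there are two Humax records (positions row and inter-row,
#' pooled size class, EOM excluded) and two Puerckhauer records (within-row,
#' coarse and fine size classes, no exclusion): 144 planned observations.
#'
#' @return A tibble of 144 design rows (no measurements).
#' @export
build_design <- function() {
  plots <- tibble::tibble(
    plot_id = sprintf("P%02d", 1:12),
    treatment = rep(rootmix_treatments, each = 4),
    block = rep(1:4, times = 3)
  )
  streams <- dplyr::bind_rows(
    tidyr::expand_grid(
      method = "humax", position = rootmix_positions,
      size_class = "pooled", eom_excluded = TRUE
    ),
    tidyr::expand_grid(
      method = "puerckhauer", position = "row",
      size_class = c("coarse", "fine"), eom_excluded = FALSE
    )
  )
  design <- tidyr::expand_grid(plots, depth = rootmix_depths, streams)
  design$sample_id <- paste(
    design$plot_id, design$depth,
    ifelse(design$method == "humax", "hx", "pk"),
    ifelse(design$method == "humax", design$position, design$size_class),
    sep = "_"
  )
  design[, c(
    "sample_id", "plot_id", "treatment", "block", "depth", "position",
    "method", "size_class", "eom_excluded"
  )]
}

#' Draw latent true fractions for a design
#'
#' Applies the scenario's logit-scale model: baseline plus the applicable
#' factor offsets (the position offset applies to Humax records, the
#' size-class offset to Puerckhauer records, and the exclusion offset to
#' EOM-excluded records) plus logit-normal noise.
#'
#' @param design Design table from [build_design()].
#' @param scenario A `rootmix_scenario`.
#' @param seed Integer seed.
#' @return The design with an added `true_fraction` column, strictly in
#'   (0, 1).
#' @export
draw_true_fractions <- function(design, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "rootmix_scenario"))
  eff <- scenario$effects
  eta <- qlogis(scenario$baseline_fraction) +
    eff$treatment[design$treatment] +
    eff$depth[design$depth] +
    eff$position[design$position] +
    eff$size_class[design$size_class] +
    eff$exclusion[ifelse(design$eom_excluded, "yes", "no")]
  noise <- withr::with_seed(seed, {
    rnorm(nrow(design), 0, scenario$dispersion_logit)
  })
  out <- design
  out$true_fraction <- plogis(unname(eta) + noise)
  out
}

#' Synthesize measured delta-13C values from true fractions
#'
#' Each sample receives its own realized endmember signatures (biological
#' heterogeneity between samples' root and EOM material):
#' `realized_root ~ N(root mean, root sd)`,
#' `realized_eom ~ N(eom mean, eom sd)`, and the measured value is
#' `f * realized_root + (1 - f) * realized_eom + N(0, sigma_instrument)`.
#' Dry masses are assigned from the scenario's fine-to-coarse mass ratio for
#' the Puerckhauer size classes (coarse 0.5 g as an arbitrary scale; only the
#' ratio matters for pooling) and 1 g for Humax pooled records.
#'
#' @param true_samples Output of [draw_true_fractions()].
#' @param scenario A `rootmix_scenario`.
#' @param seed Integer seed.
#' @return A sample table carrying, in addition to the measurement schema,
#'   the latent columns `true_fraction`, `realized_root_delta`,
#'   `realized_eom_delta` for recovery testing.
#' @export
synthesize_delta13c <- function(true_samples, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "rootmix_scenario"))
  n <- nrow(true_samples)
  f <- true_samples$true_fraction
  draws <- withr::with_seed(seed, {
    list(
      root = rnorm(n, scenario$root_endmember["mean"], scenario$root_endmember["sd"]),
      eom = rnorm(n, scenario$eom_endmember["mean"], scenario$eom_endmember["sd"]),
      meas = rnorm(n, 0, scenario$sigma_instrument)
    )
  })
  out <- true_samples
  out$realized_root_delta <- draws$root
  out$realized_eom_delta <- draws$eom
  out$delta13c <- f * draws$root + (1 - f) * draws$eom + draws$meas
  out$dry_mass <- dplyr::case_when(
    out$method == "humax" ~ 1.0,
    out$size_class == "coarse" ~ 0.5,
    out$size_class == "fine" ~ 0.5 * scenario$mass_ratio_fine_to_coarse
  )
  out$c_concentration <- NA_real_
  new_sample_table(out, provenance = "synthetic")
}

#' Remove observations at random
#'
#' Emulates field/lab losses by deleting `n_missing` uniformly random rows.
#'
#' @param table A sample table.
#' @param n_missing Number of rows to remove (must be < `nrow(table)`).
#' @param seed Integer seed.
#' @return The table without the removed rows.
#' @export
apply_missingness <- function(table, n_missing, seed = 1L) {
  if (n_missing >= nrow(table)) {
    abort_numeric("n_missing must be smaller than the table size")
  }
  if (n_missing == 0) {
    return(table)
  }
  drop <- withr::with_seed(seed, sample.int(nrow(table), n_missing))
  table[-drop, , drop = FALSE]
}

#' Generate a reference ley fine-root delta-13C table
#'
#' Emulates the prior-year grass-clover ley dataset used to derive the EOM
#' endmember: `n` values drawn from the scenario's EOM distribution, labeled
#' round-robin across the 12 plots.
#'
#' @param scenario A `rootmix_scenario`.
#' @param n Number of reference samples (default 12; minimum 2).
#' @param seed Integer seed.
#' @return A tibble `sample_id, plot_id, treatment, delta13c`.
#' @export
generate_reference_ley <- function(scenario, n = 12, seed = scenario$seed) {
  stopifnot(inherits(scenario, "rootmix_scenario"))
  if (n < 2) abort_numeric("need at least 2 reference samples")
  design <- build_design()
  plots <- design[!duplicated(design$plot_id), c("plot_id", "treatment")]
  idx <- rep(seq_len(nrow(plots)), length.out = n)
  values <- withr::with_seed(seed, {
    rnorm(n, scenario$eom_endmember["mean"], scenario$eom_endmember["sd"])
  })
  tibble::tibble(
    sample_id = sprintf("LEY%02d", seq_len(n)),
    plot_id = plots$plot_id[idx],
    treatment = plots$treatment[idx],
    delta13c = values
  )
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generative chain: design, latent true fractions, realized
#' delta-13C measurements, missingness, and the reference ley table. All
#' randomness derives from a single seed, so results are reproducible.
#'
#' @param scenario A `rootmix_scenario` (default [dok2013_scenario()]).
#' @param seed Integer seed (default: the scenario's).
#' @param n_reference Size of the reference ley table (default 12).
#' @return A list with `samples` (measurement schema columns only), `truth`
#'   (retained rows with latent columns), `reference`, and the `scenario`.
#' @export
simulate_study <- function(scenario = dok2013_scenario(),
                           seed = scenario$seed, n_reference = 12) {
  design <- build_design()
  truths <- draw_true_fractions(design, scenario, seed = seed)
  full <- synthesize_delta13c(truths, scenario, seed = seed + 1000L)
  kept <- apply_missingness(full, scenario$n_missing, seed = seed + 2000L)
  reference <- generate_reference_ley(scenario, n = n_reference, seed = seed + 3000L)
  samples <- kept[, names(empty_sample_tibble())]
  list(
    samples = new_sample_table(samples, provenance = "synthetic"),
    truth = kept,
    reference = reference,
    scenario = scenario
  )
}

#' Read or write a scenario as flat key-value text (YAML)
#'
#' Scenario files are flat `key: value` YAML; effect offsets use keys of the
#' form `effect_<factor>_<level>`. A packaged baseline file is available at
#' `system.file("extdata", "dok2013_scenario.yml", package = "rootmix")`.
#'
#' @param path File path.
#' @return For `read_scenario()`, a `rootmix_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort_schema(sprintf("scenario file not found: %s", path))
  }
  kv <- yaml::read_yaml(path)
  effects <- list()
  known_factors <- c("treatment", "depth", "position", "size_class", "exclusion")
  for (key in grep("^effect_", names(kv), value = TRUE)) {
    rest <- sub("^effect_", "", key)
    fac <- known_factors[startsWith(rest, paste0(known_factors, "_"))]
    if (length(fac) != 1) {
      abort_schema(sprintf("malformed effect key '%s'", key))
    }
    lev <- sub(paste0("^", fac, "_"), "", rest)
    effects[[fac]] <- c(effects[[fac]], stats::setNames(as.numeric(kv[[key]]), lev))
  }
  scenario(
    baseline_fraction = kv$baseline_fraction %||% 0.5,
    effects = effects,
    dispersion_logit = kv$dispersion_logit %||% 0.9,
    root_endmember = c(kv$root_mean %||% -13.3, kv$root_sd %||% 0.5),
    eom_endmember = c(kv$eom_mean %||% -29.3, kv$eom_sd %||% 0.3),
    sigma_instrument = kv$sigma_instrument %||% 0.2,
    n_missing = kv$n_missing %||% 5L,
    mass_ratio_fine_to_coarse = kv$mass_ratio_fine_to_coarse %||% 1.82,
    seed = kv$seed %||% 1L
  )
}

#' @rdname read_scenario
#' @param scenario A `rootmix_scenario` to serialize.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "rootmix_scenario"))
  kv <- list(
    baseline_fraction = scenario$baseline_fraction,
    dispersion_logit = scenario$dispersion_logit,
    root_mean = unname(scenario$root_endmember["mean"]),
    root_sd = unname(scenario$root_endmember["sd"]),
    eom_mean = unname(scenario$eom_endmember["mean"]),
    eom_sd = unname(scenario$eom_endmember["sd"]),
    sigma_instrument = scenario$sigma_instrument,
    n_missing = scenario$n_missing,
    mass_ratio_fine_to_coarse = scenario$mass_ratio_fine_to_coarse,
    seed = scenario$seed
  )
  for (fac in names(scenario$effects)) {
    for (lev in names(scenario$effects[[fac]])) {
      val <- scenario$effects[[fac]][[lev]]
      if (val != 0) kv[[paste("effect", fac, lev, sep = "_")]] <- val
    }
  }
  yaml::write_yaml(kv, path)
  invisible(path)
}
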