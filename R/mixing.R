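#' Two-pool mass-balance mixing fraction
#'
#' Partitions a measured delta-13C value between the two source pools:
#' `raw_fraction = (delta_s - eom_mean) / (root_mean - eom_mean)` is the mass
#' fraction of recent root biomass C of total C in the sample; the EOM C
#' fraction is its complement (`1 - fraction`). The raw value may fall
#' outside \[0, 1\] when a sample is isotopically lighter than the EOM
#' endmember or heavier than the root endmember; `fraction` is the value
#' clamped to \[0, 1\] and `flag` records whether clamping occurred
#' (`in_range`, `clamped_low`, `clamped_high`). Raw values are preserved for
#' audit.
#'
#' @param delta_s Measured sample delta-13C (per mil vs V-PDB); vectorized.
#' @param pair An [endmember_pair()].
#' @return A tibble with columns `raw_fraction`, `fraction`, `flag`.
#' @export
mixing_fraction <- function(delta_s, pair) {
  stopifnot(inherits(pair, "endmember_pair"))
  raw <- (delta_s - pair$eom$mean) / pair$separation
  fraction <- pmin(1, pmax(0, raw))
  flag <- dplyr::case_when(
    raw > 1 ~ "clamped_high",
    raw < 0 ~ "clamped_low",
    TRUE ~ "in_range"
  )
  tibble::tibble(raw_fraction = raw, fraction = fraction, flag = flag)
}

#' First-order (delta-method) standard error of the mixing fraction
#'
#' Propagates the three independent variance sources -- sample measurement,
#' root endmember, EOM endmember -- through the mixing equation at the raw
#' (unclamped) point:
#' \deqn{SE = \sqrt{(\sigma_s/\Delta)^2 +
#'   (\sigma_{RB} (\delta_s - \mu_{EOM})/\Delta^2)^2 +
#'   (\sigma_{EOM} (\delta_s - \mu_{RB})/\Delta^2)^2}}
#' with \eqn{\Delta} the endmember separation.
#'
#' @param delta_s Measured sample delta-13C (per mil); vectorized.
#' @param pair An [endmember_pair()]; its `sd` fields supply the endmember
#'   uncertainties.
#' @param sigma_s Per-sample measurement SD in per mil (default 0.2, the
#'   typical IRMS analytical precision for plant biomass).
#' @return Dimensionless standard error(s) of the fraction.
#' @export
analytic_se <- function(delta_s, pair, sigma_s = 0.2) {
  stopifnot(inherits(pair, "endmember_pair"))
  if (sigma_s < 0) abort_numeric("sigma_s must be non-negative")
  d <- pair$separation
  sqrt(
    (sigma_s / d)^2 +
      (pair$root$sd * (delta_s - pair$eom$mean) / d^2)^2 +
      (pair$eom$sd * (delta_s - pair$root$mean) / d^2)^2
  )
}

#' Monte-Carlo uncertainty of the mixing fraction
#'
#' Draws Gaussian perturbations of the sample value and both endmember means
#' with their respective SDs, recomputes the raw fraction per draw, clamps
#' each draw to \[0, 1\], and reports the 2.5/97.5 percentile interval and
#' the SD of the clamped draws. Draws whose perturbed endmember separation
#' falls below 0.1 per mil in absolute value are rejected and redrawn (the
#' count is reported). Deterministic given the seed.
#'
#' In the linear regime (all SDs much smaller than the separation, point
#' estimate well inside \[0, 1\]) `se_mc` converges to [analytic_se()].
#'
#' @param delta_s Measured sample delta-13C (per mil); scalar.
#' @param pair An [endmember_pair()].
#' @param sigma_s Sample measurement SD (per mil).
#' @param draws Number of Monte-Carlo draws (minimum 1000; default 10000).
#' @param seed Integer seed.
#' @return A list with `ci_low`, `ci_high`, `se_mc`, `n_rejected`.
#' @export
mc_uncertainty <- function(delta_s, pair, sigma_s = 0.2, draws = 10000,
                           seed = 1L) {
  stopifnot(inherits(pair, "endmember_pair"), length(delta_s) == 1)
  if (draws < 1000) abort_numeric("draws must be at least 1000")
  withr::with_seed(seed, {
    sim <- mc_draw_fractions(delta_s, pair, sigma_s, draws)
  })
  ci <- unname(stats::quantile(sim$fractions, c(0.025, 0.975), type = 7))
  list(
    ci_low = ci[1], ci_high = ci[2],
    se_mc = stats::sd(sim$fractions), n_rejected = sim$n_rejected
  )
}

# Draw `draws` clamped fractions for one sample; assumes an active RNG state.
mc_draw_fractions <- function(delta_s, pair, sigma_s, draws) {
  s <- rnorm(draws, delta_s, sigma_s)
  r <- rnorm(draws, pair$root$mean, pair$root$sd)
  e <- rnorm(draws, pair$eom$mean, pair$eom$sd)
  n_rejected <- 0L
  repeat {
    bad <- which(abs(r - e) < 0.1)
    if (length(bad) == 0) break
    n_rejected <- n_rejected + length(bad)
    r[bad] <- rnorm(length(bad), pair$root$mean, pair$root$sd)
    e[bad] <- rnorm(length(bad), pair$eom$mean, pair$eom$sd)
  }
  raw <- (s - e) / (r - e)
  list(fractions = pmin(1, pmax(0, raw)), n_rejected = n_rejected)
}

#' Mass-weighted pooling of coarse and fine size-class fractions
#'
#' Root fractions for an (unmeasured) pooled Puerckhauer size class are
#' synthesized as the weighted average of the coarse and fine fractions with
#' respect to their dry masses, or dry carbon masses when carbon
#' concentrations are supplied for both classes.
#'
#' @param f_coarse,f_fine Fractions in \[0, 1\].
#' @param mass_coarse,mass_fine Dry masses in grams (non-negative, not both
#'   zero).
#' @param c_conc_coarse,c_conc_fine Optional carbon mass fractions in
#'   \[0, 1\]; used as additional weights only when both are given.
#' @return The pooled fraction, always within
#'   `[min(f_coarse, f_fine), max(f_coarse, f_fine)]`.
#' @export
pool_size_classes <- function(f_coarse, f_fine, mass_coarse, mass_fine,
                              c_conc_coarse = NULL, c_conc_fine = NULL) {
  if (any(mass_coarse < 0) || any(mass_fine < 0)) {
    abort_numeric("masses must be non-negative")
  }
  w_c <- mass_coarse
  w_f <- mass_fine
  if (!is.null(c_conc_coarse) && !is.null(c_conc_fine) &&
    all(!is.na(c_conc_coarse)) && all(!is.na(c_conc_fine))) {
    w_c <- w_c * c_conc_coarse
    w_f <- w_f * c_conc_fine
  }
  if (any(w_c + w_f <= 0)) {
    abort_numeric("cannot pool size classes: both weights are zero")
  }
  (w_c * f_coarse + w_f * f_fine) / (w_c + w_f)
}

#' Apply the mixing model to a whole sample table
#'
#' Computes one mixing result per measured sample and, in addition,
#' synthesizes Puerckhauer "pooled" records via [pool_size_classes()]
#' wherever a plot x depth cell has both a coarse and a fine result with dry
#' masses available (cells lacking a mass are skipped with a warning). The
#' synthesized records carry `source = "pooled"` and a sample id of the form
#' `<plot>_<depth>_pk_pooled`; they are what the EOM-exclusion comparison
#' (Humax pooled, excluded vs Puerckhauer pooled, not excluded) relies on.
#'
#' Confidence intervals: with `draws >= 1000` a per-sample Monte-Carlo
#' interval is computed ([mc_uncertainty()]); with `draws = 0` a normal
#' approximation `fraction +/- 1.96 SE` clamped to \[0, 1\] is used, which is
#' much faster for replicate studies. Pooled records always use the normal
#' approximation with a mass-weighted SE (endmember-induced correlation
#' between the coarse and fine fractions is ignored, making the pooled SE
#' slightly conservative near the bounds).
#'
#' @param table A validated sample table.
#' @param pair An [endmember_pair()].
#' @param sigma_s Sample measurement SD in per mil (default 0.2).
#' @param draws Monte-Carlo draws per sample (0 = analytic intervals).
#' @param seed Integer seed for the Monte-Carlo step.
#' @return A tibble: design columns, `source` (`"measured"` or `"pooled"`),
#'   `raw_fraction`, `fraction`, `se_analytic`, `ci_low`, `ci_high`, `flag`.
#' @export
run_mixing <- function(table, pair, sigma_s = 0.2, draws = 0, seed = 1L) {
  stopifnot(inherits(pair, "endmember_pair"))
  if (nrow(table) == 0) abort_schema("sample table is empty")
  mix <- mixing_fraction(table$delta13c, pair)
  se <- analytic_se(table$delta13c, pair, sigma_s)

  if (draws > 0) {
    if (draws < 1000) abort_numeric("draws must be 0 (analytic) or >= 1000")
    ci <- withr::with_seed(seed, {
      t(vapply(table$delta13c, function(d) {
        sim <- mc_draw_fractions(d, pair, sigma_s, draws)
        unname(stats::quantile(sim$fractions, c(0.025, 0.975), type = 7))
      }, numeric(2)))
    })
    ci_low <- ci[, 1]
    ci_high <- ci[, 2]
  } else {
    ci_low <- pmax(0, mix$fraction - 1.96 * se)
    ci_high <- pmin(1, mix$fraction + 1.96 * se)
  }

  measured <- dplyr::bind_cols(
    table[, intersect(names(empty_sample_tibble()), names(table))],
    tibble::tibble(
      source = "measured",
      raw_fraction = mix$raw_fraction, fraction = mix$fraction,
      se_analytic = se, ci_low = ci_low, ci_high = ci_high, flag = mix$flag
    )
  )

  pooled <- synthesize_pooled_records(measured)
  dplyr::bind_rows(measured, pooled)
}

# Build Puerckhauer pooled records from per-cell coarse/fine pairs.
synthesize_pooled_records <- function(measured) {
  pk <- dplyr::filter(
    measured,
    .data$method == "puerckhauer", .data$size_class %in% c("coarse", "fine")
  )
  if (nrow(pk) == 0) {
    return(measured[0, ])
  }
  wide <- tidyr::pivot_wider(
    pk,
    id_cols = c("plot_id", "treatment", "block", "depth", "position"),
    names_from = "size_class",
    values_from = c("fraction", "raw_fraction", "se_analytic", "dry_mass", "c_concentration")
  )
  needed <- c(
    "fraction_coarse", "fraction_fine", "dry_mass_coarse", "dry_mass_fine"
  )
  for (col in needed) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  complete <- !is.na(wide$fraction_coarse) & !is.na(wide$fraction_fine)
  has_mass <- complete &
    !is.na(wide$dry_mass_coarse) & !is.na(wide$dry_mass_fine) &
    (wide$dry_mass_coarse + wide$dry_mass_fine) > 0
  n_skipped <- sum(complete & !has_mass)
  if (n_skipped > 0) {
    warn(sprintf(
      "%d plot x depth cell(s) skipped when pooling size classes: dry mass missing",
      n_skipped
    ))
  }
  wide <- wide[has_mass, , drop = FALSE]
  if (nrow(wide) == 0) {
    return(measured[0, ])
  }
  w_c <- wide$dry_mass_coarse
  w_f <- wide$dry_mass_fine
  use_conc <- !is.na(wide$c_concentration_coarse) &
    !is.na(wide$c_concentration_fine)
  w_c[use_conc] <- w_c[use_conc] * wide$c_concentration_coarse[use_conc]
  w_f[use_conc] <- w_f[use_conc] * wide$c_concentration_fine[use_conc]
  wt_c <- w_c / (w_c + w_f)
  wt_f <- w_f / (w_c + w_f)

  fraction <- wt_c * wide$fraction_coarse + wt_f * wide$fraction_fine
  raw <- wt_c * wide$raw_fraction_coarse + wt_f * wide$raw_fraction_fine
  se <- sqrt((wt_c * wide$se_analytic_coarse)^2 +
    (wt_f * wide$se_analytic_fine)^2)
  tibble::tibble(
    sample_id = paste(wide$plot_id, wide$depth, "pk_pooled", sep = "_"),
    plot_id = wide$plot_id,
    treatment = wide$treatment,
    block = wide$block,
    depth = wide$depth,
    position = wide$position,
    method = "puerckhauer",
    size_class = "pooled",
    eom_excluded = FALSE,
    delta13c = NA_real_,
    dry_mass = wide$dry_mass_coarse + wide$dry_mass_fine,
    c_concentration = NA_real_,
    source = "pooled",
    raw_fraction = raw,
    fraction = fraction,
    se_analytic = se,
    ci_low = pmax(0, fraction - 1.96 * se),
    ci_high = pmin(1, fraction + 1.96 * se),
    flag = "in_range"
  )
}
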