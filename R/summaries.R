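#' Factorial group summaries of mixing fractions
#'
#' Per-cell mean, standard error (sample SD / sqrt(n), with the n - 1
#' denominator) and count of the clamped fractions, for any combination of
#' design factors. Cells with a single observation report no SE (rather than
#' 0). Cells are ordered by canonical factor levels.
#'
#' @param results Mixing results joined to the design (from [run_mixing()]).
#' @param factors Character vector of factor column names to group by.
#' @return A tibble with one row per populated cell: the factor levels,
#'   `mean`, `se`, `n`.
#' @export
summarize_fractions <- function(results, factors) {
  unknown <- setdiff(factors, names(results))
  if (length(unknown) > 0) {
    abort_schema(sprintf(
      "unknown factor(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  ordered <- order_factor_levels(results, factors)
  out <- dplyr::summarise(
    dplyr::group_by(ordered, dplyr::across(dplyr::all_of(factors))),
    mean = mean(.data$fraction),
    se = ifelse(dplyr::n() > 1,
      stats::sd(.data$fraction) / sqrt(dplyr::n()), NA_real_
    ),
    n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(factors)))
  for (f in factors) out[[f]] <- as.character(out[[f]])
  out
}

order_factor_levels <- function(results, factors) {
  canonical <- list(
    treatment = rootmix_treatments, depth = rootmix_depths,
    position = rootmix_positions, method = rootmix_methods,
    size_class = rootmix_size_classes
  )
  for (f in factors) {
    if (f %in% names(canonical)) {
      results[[f]] <- factor(results[[f]],
        levels = intersect(canonical[[f]], unique(results[[f]]))
      )
    }
  }
  results
}

#' Treatment x depth summary grid of root-C fractions
#'
#' Renders the per-depth, per-treatment means of the recent-root C fraction
#' as a grid of `"mean +/- se (n)"` strings, depths as rows (with their meter
#' ranges) and treatments as columns. Treatments absent from the results are
#' omitted with a warning.
#'
#' @param results Mixing results joined to the design.
#' @return A tibble: `depth` column plus one formatted column per treatment.
#' @export
report_table2 <- function(results) {
  cells <- summarize_fractions(results, c("depth", "treatment"))
  missing_treat <- setdiff(rootmix_treatments, unique(cells$treatment))
  if (length(missing_treat) > 0) {
    warn(sprintf(
      "treatment(s) with no data omitted: %s",
      paste(missing_treat, collapse = ", ")
    ))
  }
  cells$cell <- format_mean_se_n(cells$mean, cells$se, cells$n)
  wide <- tidyr::pivot_wider(
    cells[, c("depth", "treatment", "cell")],
    names_from = "treatment", values_from = "cell"
  )
  wide$depth <- unname(rootmix_depth_labels[wide$depth])
  wide
}

#' Format a summary cell as "mean +/- se (n)"
#'
#' @param mean,se,n Cell statistics; `se = NA` (n = 1) omits the spread term.
#' @return Character vector like `"0.44 ± 0.07 (16)"`.
#' @export
format_mean_se_n <- function(mean, se, n) {
  ifelse(
    is.na(se),
    sprintf("%.2f (%d)", mean, as.integer(n)),
    sprintf("%.2f ± %.2f (%d)", mean, se, as.integer(n))
  )
}

# ---------------------------------------------------------------------------
# Design-respecting permutation tests
#
# The field layout is a split design: treatment is a whole-plot factor (12
# plots), depth varies within plots, and position / size class / EOM
# exclusion vary within plot x depth cells. Each factor is therefore permuted
# at its own experimental unit, within the stratum where units are
# exchangeable under the null:
#   treatment    unit = plot,          stratum = study (or block)
#   depth        unit = plot x depth,  stratum = plot
#   others       unit = sample row,    stratum = plot x depth
# The test statistic is the between-level mean square of unit-level values
# (unit value = mean fraction over the unit's rows).
# ---------------------------------------------------------------------------

permutation_units <- function(results, factor, within_blocks = FALSE) {
  if (!factor %in% names(results)) {
    abort_schema(sprintf("unknown factor: %s", factor))
  }
  if (factor == "treatment") {
    unit_key <- results$plot_id
    stratum <- if (within_blocks) as.character(results$block) else rep("all", nrow(results))
  } else if (factor == "depth") {
    unit_key <- paste(results$plot_id, results$depth, sep = "|")
    stratum <- results$plot_id
  } else if (factor %in% c("position", "size_class", "eom_excluded")) {
    unit_key <- results$sample_id
    stratum <- paste(results$plot_id, results$depth, sep = "|")
  } else {
    abort_schema(sprintf("no permutation scheme defined for factor '%s'", factor))
  }
  df <- tibble::tibble(
    unit = unit_key, stratum = stratum,
    label = as.character(results[[factor]]), y = results$fraction
  )
  units <- dplyr::summarise(
    dplyr::group_by(df, .data$unit, .data$stratum, .data$label),
    y = mean(.data$y), .groups = "drop"
  )
  if (anyDuplicated(units$unit) > 0) {
    abort_schema(sprintf(
      "factor '%s' is not constant within its experimental unit", factor
    ))
  }
  units
}

# Number of distinct label arrangements: product over strata of multinomial
# coefficients.
count_distinct_perms <- function(units) {
  per_stratum <- vapply(split(units$label, units$stratum), function(lab) {
    n <- length(lab)
    cnt <- table(lab)
    exp(lgamma(n + 1) - sum(lgamma(cnt + 1)))
  }, numeric(1))
  prod(per_stratum)
}

# All distinct permutations of a label vector (small n only).
distinct_label_perms <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(remaining) {
    if (length(remaining) == 1) {
      return(list(remaining))
    }
    out <- list()
    for (lv in unique(remaining)) {
      rest <- remaining[-match(lv, remaining)]
      for (tail in recurse(rest)) out[[length(out) + 1L]] <- c(lv, tail)
    }
    out
  }
  recurse(labels)
}

# Enumerate distinct permuted label vectors across all strata (cross product).
enumerate_stratified_perms <- function(units) {
  idx_by_stratum <- split(seq_len(nrow(units)), units$stratum)
  per_stratum <- lapply(idx_by_stratum, function(idx) {
    distinct_label_perms(units$label[idx])
  })
  combos <- expand.grid(
    lapply(per_stratum, seq_along),
    KEEP.OUT.ATTRS = FALSE
  )
  lapply(seq_len(nrow(combos)), function(i) {
    lab <- units$label
    for (s in seq_along(idx_by_stratum)) {
      lab[idx_by_stratum[[s]]] <- per_stratum[[s]][[combos[i, s]]]
    }
    lab
  })
}

permute_within_strata <- function(labels, idx_by_stratum) {
  for (idx in idx_by_stratum) {
    labels[idx] <- labels[idx][sample.int(length(idx))]
  }
  labels
}

#' Permutation test for a main effect, respecting the sampling design
#'
#' Tests whether mean fractions differ between the levels of one design
#' factor. The statistic is the between-level mean square of unit-level mean
#' fractions; the null distribution is built by permuting the factor at its
#' proper experimental unit: treatment across whole plots, depth within
#' plots, and position / size class / EOM exclusion within plot x depth
#' cells. When fewer than 20 distinct permutations exist the full set is
#' enumerated instead of sampled (noted in the result).
#'
#' This is an assumption-light replacement for a mixed-model ANOVA: the
#' p-value is `(1 + #\{permuted >= observed\}) / (B + 1)` and is never
#' smaller than `1 / (B + 1)`.
#'
#' @param results Mixing results joined to the design (typically one of the
#'   [build_subsets()] subsets).
#' @param factor One of `"treatment"`, `"depth"`, `"position"`,
#'   `"size_class"`, `"eom_excluded"`.
#' @param B Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param within_blocks If `TRUE`, treatment labels are permuted within field
#'   blocks instead of across the whole study.
#' @param subset_name Optional label recorded in the result.
#' @return A one-row tibble: `subset_name`, `effect`, `statistic`, `p_perm`,
#'   `B`, `seed`, `exact`.
#' @export
permutation_main_effect <- function(results, factor, B = 9999, seed = 1L,
                                    within_blocks = FALSE,
                                    subset_name = NA_character_) {
  units <- permutation_units(results, factor, within_blocks)
  if (length(unique(units$label)) < 2) {
    abort_schema(sprintf("factor '%s' has fewer than 2 levels", factor))
  }
  observed <- between_group_ms(units$y, units$label)
  n_distinct <- count_distinct_perms(units)

  if (n_distinct < 20) {
    inform(sprintf(
      "only %d distinct permutations; using exact enumeration", round(n_distinct)
    ))
    perms <- enumerate_stratified_perms(units)
    stats <- vapply(perms, function(lab) between_group_ms(units$y, lab), numeric(1))
    p <- sum(stats >= observed - 1e-12) / length(stats)
    B_used <- length(stats)
    exact <- TRUE
  } else {
    idx_by_stratum <- split(seq_len(nrow(units)), units$stratum)
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(B), function(i) {
        lab <- permute_within_strata(units$label, idx_by_stratum)
        between_group_ms(units$y, lab) >= observed - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (B + 1)
    B_used <- B
    exact <- FALSE
  }
  tibble::tibble(
    subset_name = subset_name, effect = factor, statistic = observed,
    p_perm = p, B = as.integer(B_used), seed = as.integer(seed), exact = exact
  )
}

#' Permutation test for a two-factor interaction (Freedman-Lane)
#'
#' Tests for non-additivity of two design factors. The statistic is an
#' interaction mean square built from cell-mean contrasts,
#' `sum n_ab (ybar_ab - abar_a - bbar_b + ybar)^2 / ((k_a - 1)(k_b - 1))`,
#' where `abar_a` and `bbar_b` are unweighted means of cell means. The null
#' distribution follows the Freedman-Lane scheme: residuals from the additive
#' fit `y ~ a + b` are permuted, added back to the additive fitted values,
#' and the interaction statistic is recomputed. All cells of the a x b cross
#' must be populated.
#'
#' @param results Mixing results joined to the design.
#' @param factor_a,factor_b Factor column names, each with at least 2 levels.
#' @param B Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param subset_name Optional label recorded in the result.
#' @return A one-row tibble as in [permutation_main_effect()], with `effect`
#'   of the form `"a:b"`.
#' @export
permutation_interaction <- function(results, factor_a, factor_b, B = 9999,
                                    seed = 1L, subset_name = NA_character_) {
  for (f in c(factor_a, factor_b)) {
    if (!f %in% names(results)) abort_schema(sprintf("unknown factor: %s", f))
    if (length(unique(results[[f]])) < 2) {
      abort_schema(sprintf("factor '%s' has fewer than 2 levels", f))
    }
  }
  a <- factor(as.character(results[[factor_a]]))
  b <- factor(as.character(results[[factor_b]]))
  y <- results$fraction
  cell <- interaction(a, b, drop = FALSE)
  if (any(table(cell) == 0)) {
    abort_schema(sprintf(
      "design error: empty cell(s) in the %s x %s cross", factor_a, factor_b
    ))
  }

  interaction_ms <- function(yv) {
    cs <- rowsum(yv, cell)
    cn <- tabulate(cell)
    cm <- matrix(cs / cn, nrow = nlevels(a), ncol = nlevels(b))
    gamma <- sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + mean(cm)
    nmat <- matrix(cn, nrow = nlevels(a), ncol = nlevels(b))
    sum(nmat * gamma^2) / ((nlevels(a) - 1) * (nlevels(b) - 1))
  }

  observed <- interaction_ms(y)
  additive <- stats::lm(y ~ a + b)
  m <- stats::fitted(additive)
  r <- stats::residuals(additive)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(B), function(i) {
      interaction_ms(m + r[sample.int(length(r))]) >= observed - 1e-12
    }, logical(1)))
  })
  tibble::tibble(
    subset_name = subset_name,
    effect = paste(factor_a, factor_b, sep = ":"),
    statistic = observed,
    p_perm = (1 + exceed) / (B + 1),
    B = as.integer(B), seed = as.integer(seed), exact = FALSE
  )
}
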