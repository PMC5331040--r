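#' Endmember estimates for the two-pool mixing model
#'
#' An endmember estimate holds the mean and SD of the delta-13C signature of
#' one pure source pool, the number of values it was computed from, and a
#' human-readable record of the selection rule applied.
#'
#' @param mean Mean delta-13C (per mil vs V-PDB).
#' @param sd Standard deviation of the contributing values (per mil).
#' @param n Number of values used.
#' @param source_label `"root"` or `"eom"`.
#' @param rule Free-text description of how the values were selected.
#' @return An object of class `endmember_estimate`.
#' @export
endmember_estimate <- function(mean, sd, n, source_label, rule = "") {
  if (!source_label %in% c("root", "eom")) {
    abort_schema("source_label must be 'root' or 'eom'")
  }
  if (n < 1) abort_numeric("an endmember estimate needs at least one value")
  if (is.na(sd)) sd <- 0 # single value: no dispersion information
  if (sd < 0) abort_numeric("endmember sd must be non-negative")
  structure(
    list(
      mean = mean, sd = sd, n = as.integer(n),
      source_label = source_label, rule = rule
    ),
    class = "endmember_estimate"
  )
}

#' @export
print.endmember_estimate <- function(x, ...) {
  cat(sprintf(
    "<%s endmember> %.2f +/- %.2f per mil (n = %d)\n  rule: %s\n",
    x$source_label, x$mean, x$sd, x$n, x$rule
  ))
  invisible(x)
}

#' Pair the root and EOM endmembers
#'
#' The mixing model divides by the separation `root$mean - eom$mean`; a pair
#' is valid only if the root signature is heavier (larger delta-13C) than the
#' EOM signature by at least `min_separation` per mil. For maize after C3
#' vegetation the separation is about 16 per mil.
#'
#' @param root,eom [endmember_estimate()] objects.
#' @param min_separation Minimum allowed separation in per mil (default 2).
#' @return An object of class `endmember_pair`.
#' @export
endmember_pair <- function(root, eom, min_separation = 2) {
  stopifnot(
    inherits(root, "endmember_estimate"),
    inherits(eom, "endmember_estimate")
  )
  delta <- root$mean - eom$mean
  if (!is.finite(delta) || delta < min_separation) {
    abort_numeric(sprintf(
      "degenerate endmembers: separation %.3f per mil is below the minimum %.3f",
      delta, min_separation
    ))
  }
  structure(
    list(root = root, eom = eom, separation = delta),
    class = "endmember_pair"
  )
}

#' @export
print.endmember_pair <- function(x, ...) {
  cat(sprintf(
    "<endmember pair> root %.2f +/- %.2f (n=%d) | eom %.2f +/- %.2f (n=%d) | separation %.2f per mil\n",
    x$root$mean, x$root$sd, x$root$n,
    x$eom$mean, x$eom$sd, x$eom$n, x$separation
  ))
  invisible(x)
}

#' Estimate the recent-root endmember from coarse-root delta-13C values
#'
#' Coarse-root samples are the least contaminated stream, and their
#' delta-13C distribution's upper tail is taken to represent pure recent
#' maize roots: the estimate is the mean and SD of all values *strictly
#' larger* than the empirical `q` quantile (default 0.8) of the coarse-root
#' values. The quantile uses linear interpolation at index `1 + q(n - 1)` on
#' the sorted values (R's default type-7 definition); values exactly equal to
#' the quantile are excluded. With 34-36 distinct coarse values this selects
#' exactly 7.
#'
#' @param coarse_values Numeric vector of coarse-root delta-13C values
#'   (per mil); at least 5 required.
#' @param q Quantile in (0, 1); default 0.8.
#' @return An [endmember_estimate()] with `source_label = "root"`.
#' @export
estimate_root_endmember <- function(coarse_values, q = 0.8) {
  coarse_values <- coarse_values[!is.na(coarse_values)]
  if (length(coarse_values) < 5) {
    abort_numeric(sprintf(
      "insufficient data: need at least 5 coarse-root values, got %d",
      length(coarse_values)
    ))
  }
  if (!(q > 0 && q < 1)) abort_numeric("q must lie strictly in (0, 1)")
  threshold <- unname(stats::quantile(coarse_values, probs = q, type = 7))
  selected <- coarse_values[coarse_values > threshold]
  if (length(selected) == 0) {
    abort_numeric(
      "degenerate selection: no values strictly above the quantile (all values tied at the maximum?)"
    )
  }
  endmember_estimate(
    mean = mean(selected),
    sd = if (length(selected) > 1) stats::sd(selected) else 0,
    n = length(selected),
    source_label = "root",
    rule = sprintf(
      "values strictly > type-7 empirical %.3g-quantile (%.4f per mil) of %d coarse-root values",
      q, threshold, length(coarse_values)
    )
  )
}

#' Estimate the EOM endmember from a reference ley dataset
#'
#' The extraneous-organic-matter signature is the plain mean and SD of
#' fine-root delta-13C values from the preceding-year grass-clover ley,
#' pooled over treatments.
#'
#' @param reference_values Numeric vector of reference delta-13C values
#'   (per mil); at least 2 required.
#' @return An [endmember_estimate()] with `source_label = "eom"`.
#' @export
estimate_eom_endmember <- function(reference_values) {
  reference_values <- reference_values[!is.na(reference_values)]
  if (length(reference_values) < 2) {
    abort_numeric(sprintf(
      "insufficient data: need at least 2 reference values, got %d",
      length(reference_values)
    ))
  }
  endmember_estimate(
    mean = mean(reference_values),
    sd = stats::sd(reference_values),
    n = length(reference_values),
    source_label = "eom",
    rule = sprintf(
      "mean of all %d reference ley fine-root values, pooled over treatments",
      length(reference_values)
    )
  )
}

#' Permutation check that endmember source values do not differ across groups
#'
#' Before pooling coarse-root values over treatments and depths (or reference
#' values over treatments), it should be checked that group means do not
#' differ. This runs a one-way permutation test on the between-group mean
#' square; the result is advisory -- a significant p-value warrants a warning,
#' not an abort, since pooling proceeds regardless.
#'
#' @param values Numeric vector.
#' @param labels Parallel vector of group labels; every group needs at least
#'   2 values and there must be at least 2 groups.
#' @param B Number of label permutations (default 999; minimum 99).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return The permutation p-value `(1 + #\{permuted >= observed\}) / (B + 1)`.
#' @export
group_invariance_check <- function(values, labels, B = 999, seed = 1L) {
  if (length(values) != length(labels)) {
    abort_schema("values and labels must have the same length")
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  counts <- table(labels)
  if (length(counts) < 2 || any(counts < 2)) {
    abort_numeric("need at least 2 groups with at least 2 values each")
  }
  if (B < 99) abort_numeric("B must be at least 99")
  observed <- between_group_ms(values, labels)
  exceed <- withr::with_seed(seed, {
    sum(vapply(
      seq_len(B),
      function(i) between_group_ms(values, sample(labels)) >= observed,
      logical(1)
    ))
  })
  (1 + exceed) / (B + 1)
}

# Between-group mean square: sum_g n_g (mean_g - grand)^2 / (k - 1).
between_group_ms <- function(values, labels) {
  sums <- rowsum(values, labels)
  ns <- tabulate(factor(labels, levels = rownames(sums)))
  means <- sums / ns
  grand <- sum(sums) / length(values)
  sum(ns * (means - grand)^2) / (length(ns) - 1)
}

#' Write an endmember pair to a two-row CSV
#'
#' @param pair An [endmember_pair()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_endmembers <- function(pair, path) {
  out <- tibble::tibble(
    source_label = c(pair$root$source_label, pair$eom$source_label),
    mean = c(pair$root$mean, pair$eom$mean),
    sd = c(pair$root$sd, pair$eom$sd),
    n = c(pair$root$n, pair$eom$n),
    rule = c(pair$root$rule, pair$eom$rule)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
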