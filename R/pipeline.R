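#' Run the full partitioning pipeline on a sample table
#'
#' Convenience wrapper chaining the standard analysis:
#' \enumerate{
#'   \item estimate the recent-root endmember from the coarse Puerckhauer
#'     delta-13C values via the upper-quantile rule;
#'   \item estimate the EOM endmember by averaging the reference ley values;
#'   \item optionally run the advisory group-invariance check on the coarse
#'     values across treatments and depths (a significant result logs a
#'     warning; pooling proceeds regardless);
#'   \item compute per-sample mixing fractions with uncertainty and
#'     synthesize Puerckhauer pooled records ([run_mixing()]);
#'   \item build the four analysis subsets ([build_subsets()]).
#' }
#'
#' @param samples A validated sample table.
#' @param reference Reference ley table with a `delta13c` column, or a
#'   numeric vector of reference values.
#' @param q Quantile for the root-endmember selection rule (default 0.8).
#' @param sigma_s Sample measurement SD in per mil (default 0.2).
#' @param draws Monte-Carlo draws per sample (0 = analytic intervals).
#' @param seed Integer seed.
#' @param min_separation Minimum endmember separation in per mil (default 2).
#' @param invariance_B Permutations for the advisory invariance check
#'   (0 = skip the check, the default; use e.g. 999 for reporting runs).
#' @return A list: `pair` (the estimated [endmember_pair()]), `results`
#'   (mixing results joined to the design), `subsets` (named list from
#'   [build_subsets()]), and `invariance` (tibble of advisory p-values, or
#'   `NULL`).
#' @export
run_pipeline <- function(samples, reference, q = 0.8, sigma_s = 0.2,
                         draws = 0, seed = 1L, min_separation = 2,
                         invariance_B = 0) {
  coarse <- dplyr::filter(
    samples,
    .data$method == "puerckhauer", .data$size_class == "coarse"
  )
  if (nrow(coarse) == 0) {
    abort_numeric("no coarse-root samples available for endmember estimation")
  }
  ref_values <- if (is.numeric(reference)) reference else reference$delta13c
  root_em <- estimate_root_endmember(coarse$delta13c, q = q)
  eom_em <- estimate_eom_endmember(ref_values)
  pair <- endmember_pair(root_em, eom_em, min_separation = min_separation)

  invariance <- NULL
  if (invariance_B > 0) {
    invariance <- tibble::tibble(
      grouping = c("treatment", "depth"),
      p_perm = c(
        group_invariance_check(coarse$delta13c, coarse$treatment,
          B = invariance_B, seed = seed
        ),
        group_invariance_check(coarse$delta13c, coarse$depth,
          B = invariance_B, seed = seed + 1L
        )
      )
    )
    for (i in seq_len(nrow(invariance))) {
      if (invariance$p_perm[i] < 0.05) {
        warn(sprintf(
          "coarse-root delta-13C differs between %s groups (p = %.3f); pooling proceeds but the root endmember may be group-specific",
          invariance$grouping[i], invariance$p_perm[i]
        ))
      }
    }
  }

  results <- run_mixing(samples, pair,
    sigma_s = sigma_s, draws = draws, seed = seed
  )
  list(
    pair = pair,
    results = results,
    subsets = build_subsets(results),
    invariance = invariance
  )
}
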