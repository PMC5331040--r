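# Shared fixtures: endmember pairs and tiny sample tables built in code.

study_pair <- function(root_sd = 0, eom_sd = 0) {
  endmember_pair(
    endmember_estimate(-13.3, root_sd, 7, "root", "fixture"),
    endmember_estimate(-29.3, eom_sd, 12, "eom", "fixture")
  )
}

# A minimal valid 3-row sample table written to a temp CSV.
tiny_samples_csv <- function(path = tempfile(fileext = ".csv"),
                             delta = c(-20.0, -24.0, -15.0)) {
  tbl <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    plot_id = "P01",
    treatment = "BIOORG1",
    block = 1L,
    depth = "D1",
    position = c("row", "inter_row", "row"),
    method = c("humax", "humax", "puerckhauer"),
    size_class = c("pooled", "pooled", "coarse"),
    eom_excluded = c(TRUE, TRUE, FALSE),
    delta13c = delta,
    dry_mass = c(1, 1, 0.5),
    c_concentration = NA_real_
  )
  readr::write_csv(tbl, path, na = "")
  path
}

# One simulated baseline study plus its fitted pipeline, cached per session.
baseline_fit <- local({
  cache <- NULL
  function(seed = 101L) {
    if (is.null(cache)) {
      study <- simulate_study(dok2013_scenario(), seed = seed)
      fit <- run_pipeline(study$samples, study$reference, seed = seed)
      cache <<- list(study = study, fit = fit)
    }
    cache
  }
})
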