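#' Read a root-sample delta-13C table from CSV
#'
#' Parses and validates a flat table of per-sample records: design factors,
#' the measured delta-13C value (per mil vs V-PDB) and optional dry mass and
#' carbon concentration. Rows whose `delta13c` cell is empty are treated as
#' missing observations and dropped (complete-case handling; the sampling
#' design tolerates missing cells).
#'
#' Expected header:
#' `sample_id,plot_id,treatment,block,depth,position,method,size_class,eom_excluded,delta13c,dry_mass,c_concentration`
#'
#' Hard validity rules enforced at read time:
#' \itemize{
#'   \item `delta13c` must parse as a number and lie in \[-40, 0\] per mil;
#'   \item factor columns must use the documented vocabularies
#'     (`treatment` BIOORG1/BIOORG2/CONFYM2, `depth` D1/D2/D3, `position`
#'     row/inter_row, `method` humax/puerckhauer, `size_class`
#'     pooled/coarse/fine);
#'   \item the design key `(plot_id, depth, method, position, size_class)`
#'     must be unique.
#' }
#' Softer plausibility rules (e.g. the method/size-class pairing) are
#' reported by [validate_table()] rather than rejected here.
#'
#' @param path Path to a CSV file (UTF-8, comma separated, period decimal,
#'   one header row; missing delta-13C encoded as an empty cell).
#' @param schema_version Schema identifier; only `"1"` is defined.
#' @return A tibble of validated sample records (a sample table), with the
#'   source path recorded in the `provenance` attribute.
#' @seealso [validate_table()], [build_subsets()], [write_fractions()]
#' @export
read_samples <- function(path, schema_version = "1") {
  if (!identical(as.character(schema_version), "1")) {
    abort_schema(sprintf("unsupported samples schema version '%s'", schema_version))
  }
  if (!file.exists(path)) {
    abort_schema(sprintf("samples file not found: %s", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c(
    "sample_id", "plot_id", "treatment", "block", "depth", "position",
    "method", "size_class", "eom_excluded", "delta13c"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "samples file is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    warn("samples file contains a header but no data rows")
    return(new_sample_table(empty_sample_tibble(), provenance = path))
  }
  raw$.line <- seq_len(nrow(raw)) + 1L # header is line 1

  # Missing observations: empty delta13c cell.
  blank <- trimws(raw$delta13c) == ""
  if (any(blank)) {
    inform(sprintf("dropping %d row(s) with missing delta13c", sum(blank)))
    raw <- raw[!blank, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    warn("all rows were marked missing; returning an empty sample table")
    return(new_sample_table(empty_sample_tibble(), provenance = path))
  }

  delta <- parse_permil(raw$delta13c)
  bad <- which(is.na(delta))
  if (length(bad) > 0) {
    abort_row(sprintf(
      "unparseable delta13c value '%s' at line %d",
      raw$delta13c[bad[1]], raw$.line[bad[1]]
    ))
  }
  out_of_window <- which(delta < -40 | delta > 0)
  if (length(out_of_window) > 0) {
    abort_row(sprintf(
      "delta13c value %s at line %d is outside the validity window [-40, 0] per mil",
      format(delta[out_of_window[1]]), raw$.line[out_of_window[1]]
    ))
  }

  check_enum <- function(col, levels) {
    bad <- which(!(raw[[col]] %in% levels))
    if (length(bad) > 0) {
      abort_row(sprintf(
        "invalid %s '%s' at line %d (expected one of: %s)",
        col, raw[[col]][bad[1]], raw$.line[bad[1]], paste(levels, collapse = ", ")
      ))
    }
  }
  check_enum("treatment", rootmix_treatments)
  check_enum("depth", rootmix_depths)
  check_enum("position", rootmix_positions)
  check_enum("method", rootmix_methods)
  check_enum("size_class", rootmix_size_classes)

  block <- suppressWarnings(as.integer(raw$block))
  bad_block <- which(is.na(block) | block < 1L | block > 4L)
  if (length(bad_block) > 0) {
    abort_row(sprintf(
      "invalid block '%s' at line %d (expected an integer 1-4)",
      raw$block[bad_block[1]], raw$.line[bad_block[1]]
    ))
  }
  eom <- parse_logical(raw$eom_excluded)
  if (anyNA(eom)) {
    i <- which(is.na(eom))[1]
    abort_row(sprintf(
      "invalid eom_excluded '%s' at line %d (expected TRUE/FALSE)",
      raw$eom_excluded[i], raw$.line[i]
    ))
  }

  tbl <- tibble::tibble(
    sample_id = raw$sample_id,
    plot_id = raw$plot_id,
    treatment = raw$treatment,
    block = block,
    depth = raw$depth,
    position = raw$position,
    method = raw$method,
    size_class = raw$size_class,
    eom_excluded = eom,
    delta13c = delta,
    dry_mass = parse_optional_numeric(raw, "dry_mass"),
    c_concentration = parse_optional_numeric(raw, "c_concentration")
  )

  key <- design_key(tbl)
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    abort_integrity(sprintf("duplicate design key: %s", dup))
  }
  new_sample_table(tbl, provenance = path)
}

parse_permil <- function(x) {
  # tolerate the typographic minus sign U+2212 occasionally found in exports
  suppressWarnings(as.numeric(gsub("−", "-", trimws(x))))
}

parse_logical <- function(x) {
  x <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

parse_optional_numeric <- function(raw, col) {
  if (!col %in% names(raw)) {
    return(rep(NA_real_, nrow(raw)))
  }
  x <- trimws(raw[[col]])
  x[x %in% c("", "NA")] <- NA
  suppressWarnings(as.numeric(x))
}

empty_sample_tibble <- function() {
  tibble::tibble(
    sample_id = character(), plot_id = character(), treatment = character(),
    block = integer(), depth = character(), position = character(),
    method = character(), size_class = character(), eom_excluded = logical(),
    delta13c = numeric(), dry_mass = numeric(), c_concentration = numeric()
  )
}

new_sample_table <- function(tbl, provenance = "unknown") {
  attr(tbl, "provenance") <- provenance
  tbl
}

design_key <- function(tbl) {
  paste(tbl$plot_id, tbl$depth, tbl$method, tbl$position, tbl$size_class,
    sep = "|"
  )
}

#' Report invariant violations in a sample table
#'
#' Collects all rule violations without aborting, so callers can decide
#' whether to stop or continue. Checked rules:
#' \itemize{
#'   \item Humax cores carry the pooled size class, are EOM-excluded, and may
#'     sit within or between rows;
#'   \item Puerckhauer cores sit within rows, carry the coarse or fine size
#'     class, and are never EOM-excluded;
#'   \item delta-13C lies in the hard validity window \[-40, 0\] per mil;
#'   \item `block` and `treatment` are constant within each plot;
#'   \item the design key `(plot_id, depth, method, position, size_class)` is
#'     unique;
#'   \item if an endmember pair is supplied, delta-13C must lie within the
#'     plausible mixture range
#'     \[eom mean - 3 eom sd, root mean + 3 root sd\] (flag only; out-of-range
#'     samples are reported, never deleted).
#' }
#'
#' @param table A sample table from [read_samples()] or [simulate_study()].
#' @param pair Optional endmember pair from [endmember_pair()].
#' @return A tibble with columns `sample_id`, `rule`, `message`; zero rows
#'   means the table is clean. Validation is idempotent.
#' @export
validate_table <- function(table, pair = NULL) {
  violations <- list()
  add <- function(ids, rule, msg) {
    if (length(ids) > 0) {
      violations[[length(violations) + 1L]] <<- tibble::tibble(
        sample_id = ids, rule = rule, message = msg
      )
    }
  }

  if (nrow(table) == 0) {
    return(tibble::tibble(
      sample_id = NA_character_, rule = "non_empty",
      message = "sample table is empty after validation"
    ))
  }

  hum <- table$method == "humax"
  add(
    table$sample_id[hum & table$size_class != "pooled"],
    "humax_pooled", "humax implies size_class = pooled"
  )
  add(
    table$sample_id[hum & !table$eom_excluded],
    "humax_excluded", "humax implies eom_excluded = TRUE"
  )
  pk <- table$method == "puerckhauer"
  add(
    table$sample_id[pk & table$position != "row"],
    "puerckhauer_row", "puerckhauer implies position = row"
  )
  add(
    table$sample_id[pk & !(table$size_class %in% c("coarse", "fine"))],
    "puerckhauer_size", "puerckhauer implies size_class coarse or fine"
  )
  add(
    table$sample_id[pk & table$eom_excluded],
    "puerckhauer_no_exclusion", "puerckhauer implies eom_excluded = FALSE"
  )
  add(
    table$sample_id[table$delta13c < -40 | table$delta13c > 0],
    "delta_window", "delta13c outside the validity window [-40, 0] per mil"
  )

  per_plot <- dplyr::summarise(
    dplyr::group_by(table, .data$plot_id),
    n_treat = dplyr::n_distinct(.data$treatment),
    n_block = dplyr::n_distinct(.data$block),
    .groups = "drop"
  )
  bad_plots <- per_plot$plot_id[per_plot$n_treat > 1 | per_plot$n_block > 1]
  add(
    table$sample_id[table$plot_id %in% bad_plots],
    "plot_constant", "block and treatment must be constant within a plot"
  )

  key <- design_key(table)
  add(
    table$sample_id[key %in% key[duplicated(key)]],
    "unique_design_key",
    "duplicate (plot_id, depth, method, position, size_class) key"
  )

  if (!is.null(pair)) {
    lo <- pair$eom$mean - 3 * pair$eom$sd
    hi <- pair$root$mean + 3 * pair$root$sd
    add(
      table$sample_id[table$delta13c < lo | table$delta13c > hi],
      "mixture_range",
      sprintf(
        "delta13c outside plausible mixture range [%.2f, %.2f] per mil",
        lo, hi
      )
    )
  }

  if (length(violations) == 0) {
    return(tibble::tibble(
      sample_id = character(), rule = character(), message = character()
    ))
  }
  dplyr::bind_rows(violations)
}

#' Build the analysis subsets of a sample table
#'
#' The incomplete factorial design supports four analysis sets:
#' `full` (all records, for treatment and depth), `positions` (all Humax
#' records: row vs inter-row), `size_classes` (all Puerckhauer coarse and
#' fine records), and `exclusion` (records matched on position = row and
#' size_class = pooled across both methods; the Puerckhauer pooled records
#' are synthesized by the size-class pooling step in [run_mixing()], so this
#' subset is usually built from mixing results rather than the raw table).
#'
#' @param table A sample table or a mixing-result table carrying the design
#'   columns `method`, `position`, `size_class`. If a `source` column is
#'   present (mixing results), `full`, `positions` and `size_classes` are
#'   restricted to measured records, while `exclusion` also draws on the
#'   synthesized pooled records.
#' @return A named list of tibbles: `full`, `positions`, `size_classes`,
#'   `exclusion`. Empty subsets trigger a warning, not an error.
#' @export
build_subsets <- function(table) {
  measured <- if ("source" %in% names(table)) {
    dplyr::filter(table, .data$source == "measured")
  } else {
    table
  }
  subsets <- list(
    full = measured,
    positions = dplyr::filter(table, .data$method == "humax"),
    size_classes = dplyr::filter(
      table,
      .data$method == "puerckhauer", .data$size_class %in% c("coarse", "fine")
    ),
    exclusion = dplyr::filter(
      table,
      .data$position == "row", .data$size_class == "pooled"
    )
  )
  for (nm in names(subsets)) {
    if (nrow(subsets[[nm]]) == 0) {
      warn(sprintf("subset '%s' is empty", nm))
    }
  }
  subsets
}

#' Write mixing results to CSV
#'
#' One row per sample: the design keys followed by `raw_fraction`,
#' `fraction`, `se_analytic`, `ci_low`, `ci_high` and `flag`. Fractions are
#' serialized with four decimal places.
#'
#' @param results Mixing results from [run_mixing()]; must be non-empty.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_fractions <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort_schema("no mixing results to write")
  }
  design_cols <- intersect(
    c(
      "sample_id", "plot_id", "treatment", "block", "depth", "position",
      "method", "size_class", "eom_excluded", "source"
    ),
    names(results)
  )
  num_cols <- c("raw_fraction", "fraction", "se_analytic", "ci_low", "ci_high")
  missing <- setdiff(c(num_cols, "flag"), names(results))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "results are missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  out <- results[, c(design_cols, num_cols, "flag")]
  for (col in num_cols) {
    out[[col]] <- sprintf("%.4f", results[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a mixing-result CSV written by [write_fractions()]
#'
#' @param path Path to a fractions CSV.
#' @return A tibble with numeric fraction columns restored.
#' @export
read_fractions <- function(path) {
  if (!file.exists(path)) {
    abort_schema(sprintf("fractions file not found: %s", path))
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in c("raw_fraction", "fraction", "se_analytic", "ci_low", "ci_high")) {
    if (col %in% names(tbl)) tbl[[col]] <- as.numeric(tbl[[col]])
  }
  if ("block" %in% names(tbl)) tbl$block <- as.integer(tbl$block)
  if ("eom_excluded" %in% names(tbl)) {
    tbl$eom_excluded <- parse_logical(tbl$eom_excluded)
  }
  tbl
}

#' Write a sample table to CSV in the documented schema
#'
#' Inverse of [read_samples()]: missing delta-13C, dry mass and carbon
#' concentration are written as empty cells.
#'
#' @param table A sample table.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_samples <- function(table, path) {
  cols <- names(empty_sample_tibble())
  out <- table[, cols]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a reference-ley delta-13C table
#'
#' The EOM endmember is derived from fine roots of a prior-year grass-clover
#' ley; the reference table carries `sample_id,plot_id,treatment,delta13c`.
#'
#' @param path Path to a reference CSV.
#' @return A tibble with a numeric `delta13c` column.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort_schema(sprintf("reference file not found: %s", path))
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"delta13c" %in% names(tbl)) {
    abort_schema("reference file is missing mandatory column: delta13c")
  }
  tbl$delta13c <- parse_permil(tbl$delta13c)
  if (anyNA(tbl$delta13c)) {
    abort_row("reference file contains unparseable delta13c values")
  }
  tbl
}
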