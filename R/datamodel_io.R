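#' Pipeline configuration
#'
#' Collects the thresholds used across the pipeline stages: the rule-of-five
#' pass rule, the logBB permeability cut-off, the docking-score acceptance
#' threshold, pharmacophore matching requirements, and the permutation-test
#' size. Values are validated once here so downstream stages can trust them.
#'
#' @param seed non-negative integer master seed for every stochastic step.
#' @param ro5_min_satisfied minimum number of satisfied rule-of-five criteria
#'   (out of 5) for a compound to count as drug-like. Default 4.
#' @param logbb_threshold minimum predicted logBB for blood-brain-barrier
#'   permeability. Default -1.0.
#' @param min_total_score docking total score a binder must strictly exceed.
#'   Default 4.0.
#' @param min_matched_features integer, or `"all"`, or `NULL` (the default:
#'   all model features minus one) — how many model features a compound must
#'   map for a pharmacophore match.
#' @param n_permutations permutations for the flavor-enrichment test.
#' @param rank_include_nhits include the training-hit count among the
#'   parameters summed by [sum_ranking()]. Default `FALSE`.
#' @param superpose_before_rmsd apply optimal rigid superposition before
#'   computing pose RMSD. Default `FALSE` (poses share the receptor frame).
#' @return a `tcm_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$min_total_score
pipeline_config <- function(seed = 0L,
                            ro5_min_satisfied = 4L,
                            logbb_threshold = -1.0,
                            min_total_score = 4.0,
                            min_matched_features = NULL,
                            n_permutations = 10000L,
                            rank_include_nhits = FALSE,
                            superpose_before_rmsd = FALSE) {
  assert_that(is.numeric(seed) && length(seed) == 1 && seed >= 0,
              "`seed` must be a single non-negative integer")
  assert_that(ro5_min_satisfied >= 0 && ro5_min_satisfied <= 5,
              "`ro5_min_satisfied` must be between 0 and 5")
  assert_that(n_permutations >= 1, "`n_permutations` must be >= 1")
  if (!is.null(min_matched_features) && !identical(min_matched_features, "all")) {
    assert_that(is.numeric(min_matched_features) && min_matched_features >= 1,
                "`min_matched_features` must be a positive integer or \"all\"")
  }
  structure(list(
    seed = as.integer(seed),
    ro5_min_satisfied = as.integer(ro5_min_satisfied),
    logbb_threshold = logbb_threshold,
    min_total_score = min_total_score,
    min_matched_features = min_matched_features,
    n_permutations = as.integer(n_permutations),
    rank_include_nhits = isTRUE(rank_include_nhits),
    superpose_before_rmsd = isTRUE(superpose_before_rmsd)
  ), class = "tcm_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `tcm_config` list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals), names(formals(pipeline_config)))])
}

# column schemas for the tabular inputs; `numeric` columns accept
# thousands separators ("470,000") because published affinity tables
# print them
.schemas <- list(
  model_stats = list(
    required = c("model_id", "specificity", "n_hits", "pareto",
                 "energy", "sterics", "hbond", "mol_qry"),
    numeric  = c("specificity", "n_hits", "pareto", "energy",
                 "sterics", "hbond", "mol_qry")
  ),
  compounds = list(
    required = c("compound_id", "name", "mw", "logp", "hbd", "hba",
                 "rotb", "tpsa", "tcm_ids"),
    numeric  = c("mw", "logp", "hbd", "hba", "rotb", "tpsa")
  ),
  tcm = list(
    required = c("tcm_id", "name", "flavors", "effects"),
    numeric  = character()
  ),
  binders = list(
    required = c("compound_id", "ki_nM", "total_score"),
    numeric  = c("ki_nM", "total_score")
  )
)

parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(readr::parse_number(
    x, locale = readr::locale(grouping_mark = ",")
  ))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("column '%s': unparsable numeric value '%s' at row %d",
                  column, x[bad[1]], bad[1]))
  }
  out
}

#' Read a typed pipeline table
#'
#' Parses one of the pipeline's four tabular inputs from a delimited file
#' (TSV by default; UTF-8, header row required). Numeric fields accept
#' thousands separators, so `"470,000"` and `"470000"` parse identically.
#' Semicolon-separated multi-value fields (`tcm_ids`, `flavors`, `effects`)
#' become list-columns. Row order is preserved.
#'
#' @param path file to read.
#' @param schema one of `"model_stats"`, `"compounds"`, `"tcm"`, `"binders"`.
#' @param delim field delimiter; `"\t"` (default) or `","`.
#' @return a tibble, one row per record.
#' @export
#' @examples
#' p <- system.file("extdata", "binders_mglur4.tsv", package = "tcmflavor")
#' read_table(p, "binders")
read_table <- function(path, schema = c("model_stats", "compounds", "tcm", "binders"),
                       delim = "\t") {
  schema <- match.arg(schema)
  assert_that(file.exists(path), paste0("file not found: ", path))
  sc <- .schemas[[schema]]
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, locale = readr::locale(encoding = "UTF-8"))
  missing <- setdiff(sc$required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("schema '%s': missing column(s): %s",
                  schema, paste(missing, collapse = ", ")))
  }
  for (col in sc$numeric) df[[col]] <- parse_numeric_column(df[[col]], col)
  if (schema == "model_stats") {
    df$n_hits <- as.integer(df$n_hits)
    df$pareto <- as.integer(df$pareto)
  }
  if (schema == "compounds") {
    df$tcm_ids <- split_multi(df$tcm_ids)
    if ("features" %in% names(df)) {
      df$features <- purrr::map(df$features, parse_feature_json)
    }
  }
  if (schema == "tcm") {
    df$flavors <- split_multi(df$flavors)
    df$effects <- split_multi(df$effects)
  }
  as_tibble(df)
}

split_multi <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

join_multi <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

parse_feature_json <- function(s) {
  if (is.na(s) || s == "") return(tibble(kind = character(), x = double(),
                                         y = double(), z = double()))
  as_tibble(jsonlite::fromJSON(s))
}

#' Write a typed pipeline table
#'
#' Inverse of [read_table()]: list-columns are re-joined with semicolons and
#' the file round-trips field-for-field.
#'
#' @param df tibble as returned by [read_table()].
#' @param path output file.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, delim = "\t") {
  out <- df
  for (col in c("tcm_ids", "flavors", "effects")) {
    if (col %in% names(out) && is.list(out[[col]])) out[[col]] <- join_multi(out[[col]])
  }
  if ("features" %in% names(out) && is.list(out$features)) {
    out$features <- vapply(out$features, function(f) {
      as.character(jsonlite::toJSON(f, auto_unbox = FALSE, digits = NA))
    }, character(1))
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a ligand pose
#'
#' Reads atom coordinates (Angstrom) from a PDB file (via [bio3d::read.pdb()])
#' or an XYZ file (atom count, comment line, then `element x y z` rows).
#' Coordinates come back in file order; no heteroatom or water filtering is
#' applied — that is the caller's decision.
#'
#' @param path coordinate file.
#' @param format `"pdb"` or `"xyz"`.
#' @return a `pose_coordinates` object: list with `atom_ids` (character) and
#'   `coords` (n x 3 numeric matrix).
#' @export
read_pose <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("pose file not found: ", path))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    ids <- trimws(pdb$atom$elety)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    assert_that(length(lines) >= 1, "empty XYZ file")
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    assert_that(!is.na(n) && n >= 1, "XYZ header must be a positive atom count")
    body <- lines[-(1:2)]
    body <- body[nzchar(trimws(body))]
    if (length(body) < n) {
      abort(sprintf("XYZ atom count mismatch: header says %d, found %d rows",
                    n, length(body)))
    }
    fields <- strsplit(trimws(body[seq_len(n)]), "\\s+")
    ids <- vapply(fields, `[[`, character(1), 1)
    coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), double(3)))
    assert_that(all(is.finite(coords)), "non-numeric coordinate in XYZ body")
  }
  pose_coordinates(ids, coords)
}

#' Construct a pose from atom labels and coordinates
#'
#' @param atom_ids character vector of atom labels.
#' @param coords n x 3 numeric matrix of coordinates in Angstrom.
#' @return a `pose_coordinates` object.
#' @export
pose_coordinates <- function(atom_ids, coords) {
  coords <- as.matrix(coords)
  assert_that(nrow(coords) >= 1 && ncol(coords) == 3,
              "`coords` must be a non-empty n x 3 matrix")
  assert_that(all(is.finite(coords)), "all coordinates must be finite")
  assert_that(length(atom_ids) == nrow(coords),
              "`atom_ids` length must equal the number of coordinate rows")
  dimnames(coords) <- NULL
  structure(list(atom_ids = as.character(atom_ids), coords = coords),
            class = "pose_coordinates")
}

#' Write a pose to PDB or XYZ
#'
#' @param pose a `pose_coordinates` object.
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_pose <- function(pose, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  n <- nrow(pose$coords)
  if (format == "xyz") {
    rows <- sprintf("%s %.6f %.6f %.6f", pose$atom_ids,
                    pose$coords[, 1], pose$coords[, 2], pose$coords[, 3])
    writeLines(c(as.character(n), "pose", rows), path)
  } else {
    rows <- sprintf(
      "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n), substr(pose$atom_ids, 1, 4),
      pose$coords[, 1], pose$coords[, 2], pose$coords[, 3],
      substr(pose$atom_ids, 1, 1))
    writeLines(c(rows, "END"), path)
  }
  invisible(path)
}

#' Write a stage result to TSV or JSON
#'
#' TSV output renders floating-point columns with four decimals
#' (round-half-even), matching the pipeline's report convention; JSON output
#' keeps full precision and round-trips losslessly.
#'
#' @param result a data frame, or a list of scalars/data frames.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    assert_that(is.data.frame(result), "TSV reports require a data frame")
    out <- result
    for (col in names(out)) {
      if (is.double(out[[col]])) out[[col]] <- format_report_number(out[[col]])
      if (is.list(out[[col]])) out[[col]] <- join_multi(out[[col]])
    }
    readr::write_delim(out, path, delim = "\t")
  }
  invisible(path)
}

#' @export
print.pose_coordinates <- function(x, ...) {
  cat(sprintf("<pose_coordinates> %d atoms\n", nrow(x$coords)))
  invisible(x)
}

#' @export
print.tcm_config <- function(x, ...) {
  cat("<tcm_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
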