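#' Pareto dominance rank of candidate pharmacophore models
#'
#' A model's Pareto rank is the number of other models that strictly dominate
#' it: at least as good on every objective (direction-adjusted) and strictly
#' better on at least one. Rank 0 means no model is superior — the usual
#' requirement for a pharmacophore hypothesis not to be an accident of the
#' genetic search.
#'
#' @param models data frame of model statistics (one row per model, with a
#'   `model_id` column and one column per parameter).
#' @param objectives named character vector mapping parameter name to
#'   `"maximize"` or `"minimize"`. Default: energy minimized, specificity,
#'   sterics, hbond and mol_qry maximized.
#' @return a tibble with `model_id` and integer `pareto_rank`.
#' @export
#' @examples
#' stats <- mglur_model_stats()
#' pareto_rank(stats)
pareto_rank <- function(models,
                        objectives = c(specificity = "maximize",
                                       energy = "minimize",
                                       sterics = "maximize",
                                       hbond = "maximize",
                                       mol_qry = "maximize")) {
  assert_that(nrow(models) >= 1, "need at least one model")
  assert_that(length(objectives) >= 1, "need at least one objective")
  unknown <- setdiff(names(objectives), names(models))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  # orient every objective so larger is better
  m <- sapply(names(objectives), function(p) {
    v <- models[[p]]
    if (objectives[[p]] == "minimize") -v else v
  })
  m <- matrix(m, nrow = nrow(models))
  n <- nrow(m)
  dominated_by <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  tibble(model_id = models$model_id, pareto_rank = dominated_by)
}

#' Pre-screen pharmacophore model candidates
#'
#' Retains the models whose training-hit count matches the training-set size
#' (within `slack`) and whose Pareto rank is zero — the two qualitative
#' criteria applied before any parameter ranking.
#'
#' @param models data frame of model statistics with `n_hits` and `pareto`.
#' @param n_training number of compounds used to build the models.
#' @param slack allowed deviation of `n_hits` from `n_training` (default 0).
#' @return the retained rows, original order preserved.
#' @export
screen_model_candidates <- function(models, n_training, slack = 0L) {
  assert_that(n_training >= 1, "`n_training` must be >= 1")
  assert_that(slack >= 0, "`slack` must be >= 0")
  dplyr::filter(models, .data$pareto == 0L,
                abs(.data$n_hits - n_training) <= slack)
}

#' Competition (minimum) rank
#'
#' Best value gets rank 1; tied values share the minimum rank; the next
#' distinct value's rank is one plus the number of strictly better values.
#'
#' @param values numeric vector.
#' @param direction `"ascending"` (smallest is best, e.g. energy or Ki) or
#'   `"descending"` (largest is best, e.g. a docking score).
#' @return integer vector of ranks.
#' @export
#' @examples
#' competition_rank(c(7.2647, 7.4445, 6.6985), "descending")
competition_rank <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  assert_that(length(values) >= 1, "`values` must be nonempty")
  v <- if (direction == "descending") -values else values
  vapply(v, function(x) 1L + sum(v < x), integer(1))
}

#' Per-parameter competition ranks of model candidates
#'
#' Energy is ranked ascending (the lowest-energy model is number 1); the
#' remaining intrinsic parameters — specificity, sterics, hbond, mol_qry,
#' and optionally the training-hit count — are ranked descending (the
#' largest value is number 1). Ties share the minimum rank.
#'
#' @param candidates data frame of model statistics.
#' @param include_nhits also rank `n_hits` (descending). Default `FALSE`.
#' @return a tibble: `model_id` plus one integer rank column per parameter.
#' @export
#' @examples
#' assign_parameter_ranks(mglur_model_stats())
assign_parameter_ranks <- function(candidates, include_nhits = FALSE) {
  assert_that(nrow(candidates) >= 1, "need at least one candidate")
  params <- c("specificity", "energy", "sterics", "hbond", "mol_qry")
  if (include_nhits) params <- c(params, "n_hits")
  out <- tibble(model_id = candidates$model_id)
  for (p in params) {
    dir <- if (p == "energy") "ascending" else "descending"
    out[[p]] <- competition_rank(candidates[[p]], dir)
  }
  out
}

#' Select the optimal pharmacophore model by summed ranks
#'
#' Sums each candidate's per-parameter competition ranks; the model with the
#' lowest sum wins. Ties are broken by lower energy, then lexicographic
#' `model_id`, and flagged.
#'
#' @param candidates data frame of model statistics (rows already screened
#'   by [screen_model_candidates()], or any set of candidates).
#' @param include_nhits include the training-hit count in the sum.
#' @return a `selection_result`: list with `ranks` (tibble), `sum_ranking`
#'   (tibble of `model_id`, `sum_ranking`), `optimal_model`, `tie_broken`.
#' @export
#' @examples
#' sel <- sum_ranking(mglur_model_stats())
#' sel$optimal_model
sum_ranking <- function(candidates, include_nhits = FALSE) {
  ranks <- assign_parameter_ranks(candidates, include_nhits = include_nhits)
  rank_cols <- setdiff(names(ranks), "model_id")
  sums <- tibble(
    model_id = ranks$model_id,
    sum_ranking = as.integer(rowSums(as.matrix(ranks[rank_cols])))
  )
  best <- min(sums$sum_ranking)
  contenders <- sums$model_id[sums$sum_ranking == best]
  tie_broken <- length(contenders) > 1
  if (tie_broken) {
    energies <- candidates$energy[match(contenders, candidates$model_id)]
    contenders <- contenders[order(energies, contenders)]
  }
  structure(list(
    ranks = ranks,
    sum_ranking = dplyr::arrange(sums, .data$sum_ranking, .data$model_id),
    optimal_model = contenders[1],
    tie_broken = tie_broken,
    include_nhits = include_nhits
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> optimal model: %s (sum of ranks %d%s)\n",
              x$optimal_model,
              x$sum_ranking$sum_ranking[x$sum_ranking$model_id == x$optimal_model],
              if (x$tie_broken) ", tie broken by energy" else ""))
  print(x$sum_ranking, ...)
  invisible(x)
}

#' Construct a pharmacophore model
#'
#' A pharmacophore is a 3D arrangement of abstract chemical features —
#' positive nitrogen (NP), hydrophobe (HY), negative center (NC), acceptor
#' atom (AA), donor atom (DA), aromatic (AR) — each with a tolerance sphere.
#'
#' @param model_id label.
#' @param features data frame with columns `kind`, `x`, `y`, `z` and
#'   optionally `tolerance` (Angstrom; default 1.0 when omitted).
#' @return a `pharmacophore_model` object.
#' @export
pharmacophore_model <- function(model_id, features) {
  features <- as_tibble(features)
  assert_that(nrow(features) >= 1, "a pharmacophore needs at least one feature")
  assert_that(all(features$kind %in% FEATURE_KINDS),
              paste0("feature kinds must be among: ",
                     paste(FEATURE_KINDS, collapse = ", ")))
  if (!"tolerance" %in% names(features)) features$tolerance <- 1.0
  assert_that(all(features$tolerance > 0), "tolerances must be positive")
  structure(list(model_id = model_id, features = features),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %s: %d features (%s)\n", x$model_id,
              nrow(x$features), paste(x$features$kind, collapse = ", ")))
  invisible(x)
}

#' Match a compound's feature points against a pharmacophore model
#'
#' Searches injective assignments of model features to same-kind compound
#' features by backtracking. An assignment is feasible when every pair of
#' assigned features has compatible internal geometry:
#' `|d_model(i,j) - d_compound(i,j)| <= tolerance_i + tolerance_j`. The
#' compound matches when some feasible assignment covers at least
#' `min_matched` model features; the reported deviation is the
#' root-mean-square of the pairwise distance discrepancies of the best
#' (largest, then lowest-deviation) feasible assignment. Deterministic for
#' a given input order.
#'
#' @param compound_features data frame with columns `kind`, `x`, `y`, `z`.
#' @param model a [pharmacophore_model()].
#' @param min_matched integer, `"all"`, or `NULL` (default: all model
#'   features minus one, the usual partial-match requirement).
#' @return a `match_result`: list with `matched`, `n_features_matched`,
#'   `assignment` (integer vector, model feature index -> compound feature
#'   index, `NA` for unassigned), `rms_deviation` (Angstrom).
#' @export
match_pharmacophore <- function(compound_features, model, min_matched = NULL) {
  feats <- model$features
  nm <- nrow(feats)
  if (is.null(min_matched)) min_matched <- max(1L, nm - 1L)
  if (identical(min_matched, "all")) min_matched <- nm
  assert_that(min_matched <= nm,
              sprintf("min_matched (%d) exceeds model feature count (%d)",
                      min_matched, nm))
  cf <- as_tibble(compound_features)
  nc <- nrow(cf)
  mcoord <- as.matrix(feats[, c("x", "y", "z")])
  ccoord <- if (nc > 0) as.matrix(cf[, c("x", "y", "z")]) else matrix(0, 0, 3)
  dmod <- as.matrix(stats::dist(mcoord))
  dcmp <- if (nc > 1) as.matrix(stats::dist(ccoord)) else matrix(0, nc, nc)
  tol <- feats$tolerance

  # candidate compound features per model feature, same kind only
  cand <- lapply(seq_len(nm), function(i) which(cf$kind == feats$kind[i]))

  best <- list(size = -1L, ss = Inf, npairs = 0L, assignment = rep(NA_integer_, nm))
  assignment <- rep(NA_integer_, nm)

  recurse <- function(i, used, size, ss, npairs) {
    if (i > nm) {
      if (size > best$size || (size == best$size && ss / max(npairs, 1) <
                               best$ss / max(best$npairs, 1))) {
        best <<- list(size = size, ss = ss, npairs = npairs,
                      assignment = assignment)
      }
      return(invisible(NULL))
    }
    # prune: even assigning every remaining feature cannot beat best size
    if (size + (nm - i + 1L) < best$size) return(invisible(NULL))
    for (j in cand[[i]]) {
      if (j %in% used) next
      ok <- TRUE
      add_ss <- 0
      add_n <- 0L
      for (k in seq_len(i - 1L)) {
        jk <- assignment[k]
        if (is.na(jk)) next
        disc <- abs(dmod[i, k] - dcmp[j, jk])
        if (disc > tol[i] + tol[k]) { ok <- FALSE; break }
        add_ss <- add_ss + disc^2
        add_n <- add_n + 1L
      }
      if (ok) {
        assignment[i] <<- j
        recurse(i + 1L, c(used, j), size + 1L, ss + add_ss, npairs + add_n)
        assignment[i] <<- NA_integer_
      }
    }
    # option: leave model feature i unassigned
    recurse(i + 1L, used, size, ss, npairs)
  }
  recurse(1L, integer(), 0L, 0, 0L)

  matched <- best$size >= min_matched
  rms <- if (best$npairs > 0) sqrt(best$ss / best$npairs) else 0
  structure(list(
    matched = matched,
    n_features_matched = max(best$size, 0L),
    assignment = best$assignment,
    rms_deviation = rms
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: %d feature(s) mapped, rms %.4f A\n",
              if (x$matched) "matched" else "not matched",
              x$n_features_matched, x$rms_deviation))
  invisible(x)
}

#' Screen a compound library against a pharmacophore model
#'
#' Runs [match_pharmacophore()] over every compound and returns the library
#' annotated with the match verdict, feature count and RMS deviation.
#'
#' @param compounds compound tibble (as from [read_table()] or
#'   [generate_compound_library()]) with a `features` list-column.
#' @param model a [pharmacophore_model()].
#' @param min_matched see [match_pharmacophore()].
#' @return the input tibble plus `matched`, `n_features_matched`,
#'   `rms_deviation` columns.
#' @export
screen_library <- function(compounds, model, min_matched = NULL) {
  res <- purrr::map(compounds$features, match_pharmacophore,
                    model = model, min_matched = min_matched)
  compounds$matched <- vapply(res, `[[`, logical(1), "matched")
  compounds$n_features_matched <- vapply(res, `[[`, integer(1), "n_features_matched")
  compounds$rms_deviation <- vapply(res, `[[`, double(1), "rms_deviation")
  compounds
}

#' Bundled pharmacophore model statistics
#'
#' Intrinsic evaluation parameters of nine candidate pharmacophore models of
#' the mGluR group I orthosteric (antagonist) site, as reported for a
#' GALAHAD-style run trained on six compounds. Shipped as the package's
#' worked example for model selection.
#'
#' @return a tibble of nine models with columns `model_id`, `specificity`,
#'   `n_hits`, `pareto`, `energy`, `sterics`, `hbond`, `mol_qry`.
#' @export
#' @examples
#' sum_ranking(mglur_model_stats())
mglur_model_stats <- function() {
  read_table(system.file("extdata", "model_stats_mglur1_orthosteric.tsv",
                         package = "tcmflavor"), "model_stats")
}
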