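#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model-selection result
#'
#' @param x a `selection_result` from [sum_ranking()].
#' @param ... unused.
#' @return a long tibble: `model_id`, `parameter`, `rank`, `sum_ranking`.
#' @export
tidy.selection_result <- function(x, ...) {
  long <- tidyr::pivot_longer(x$ranks, -"model_id",
                              names_to = "parameter", values_to = "rank")
  dplyr::left_join(long, x$sum_ranking, by = "model_id")
}

#' @rdname tidy.selection_result
#' @return for `glance`: a one-row tibble with `optimal_model`,
#'   `min_sum_ranking`, `n_candidates`, `tie_broken`, `include_nhits`.
#' @export
glance.selection_result <- function(x, ...) {
  tibble(optimal_model = x$optimal_model,
         min_sum_ranking = min(x$sum_ranking$sum_ranking),
         n_candidates = nrow(x$sum_ranking),
         tie_broken = x$tie_broken,
         include_nhits = x$include_nhits)
}

#' Tidy a docking validation result
#'
#' @param x a `validation_result` from [validate_binders()].
#' @param ... unused.
#' @return a tibble of per-binder ranks when a correlation was computed,
#'   else an empty tibble.
#' @export
tidy.validation_result <- function(x, ...) {
  if (is.null(x$correlation)) {
    return(tibble(ki_rank = integer(), score_rank = integer()))
  }
  tibble(ki_rank = x$correlation$ki_ranks,
         score_rank = x$correlation$score_ranks)
}

#' @rdname tidy.validation_result
#' @return for `glance`: one row with `n_binders`, `rho`,
#'   `all_docked_above_threshold`, `min_score`.
#' @export
glance.validation_result <- function(x, ...) {
  tibble(n_binders = x$n_binders,
         rho = if (!is.null(x$correlation)) x$correlation$rho else NA_real_,
         all_docked_above_threshold = x$all_docked_above_threshold,
         min_score = x$min_score)
}

#' Tidy a flavor association result
#'
#' @param x an `association_result` from [associate_flavors()].
#' @param ... unused.
#' @return the flavor frequency/enrichment tibble with the group label.
#' @export
tidy.association_result <- function(x, ...) {
  dplyr::mutate(x$flavor_frequencies, group = x$group, .before = 1)
}

#' @rdname tidy.association_result
#' @return for `glance`: one row with `group`, `n_tcms`, `top_flavor`,
#'   `top_effect`.
#' @export
glance.association_result <- function(x, ...) {
  tibble(group = x$group, n_tcms = x$n_tcms,
         top_flavor = x$top_flavors[1] %||% NA_character_,
         top_effect = if (nrow(x$effect_ranking) > 0)
           x$effect_ranking$effect[1] else NA_character_)
}

#' Tidy a filter cascade result
#'
#' @param x a `cascade_result` from [filter_cascade()].
#' @param ... unused.
#' @return a long tibble of stage counts.
#' @export
tidy.cascade_result <- function(x, ...) {
  tibble(group = x$group,
         stage = c("pharmacophore_hits", "druglike", "bbb_permeable"),
         count = c(x$n_pharmacophore_hits, x$n_druglike, x$n_bbb_permeable))
}
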