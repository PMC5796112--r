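#' Rule-of-five drug-likeness score
#'
#' Counts how many of five drug-likeness criteria a compound satisfies —
#' molecular weight <= 500 Da, logP <= 5, hydrogen-bond donors <= 5,
#' hydrogen-bond acceptors <= 10, rotatable bonds <= 10 — with inclusive
#' boundaries. A compound passes when it satisfies at least
#' `min_satisfied` criteria (default 4 of 5).
#'
#' @param props data frame with columns `mw`, `logp`, `hbd`, `hba`, `rotb`
#'   (one row per compound), or a single-row list with those names.
#' @param min_satisfied pass threshold, 0-5 (default 4).
#' @return a tibble with integer `ro5_satisfied` and logical `ro5_pass`,
#'   one row per compound.
#' @export
#' @examples
#' lipinski_score(data.frame(mw = 400, logp = 2, hbd = 2, hba = 5, rotb = 5))
lipinski_score <- function(props, min_satisfied = 4L) {
  props <- as_tibble(props)
  satisfied <- (props$mw <= 500) + (props$logp <= 5) + (props$hbd <= 5) +
    (props$hba <= 10) + (props$rotb <= 10)
  tibble(ro5_satisfied = as.integer(satisfied),
         ro5_pass = satisfied >= min_satisfied)
}

#' Blood-brain-barrier permeability surrogate
#'
#' Predicts the log brain/blood concentration ratio with the Clark-type
#' linear model `logBB = 0.152 * logP - 0.0148 * TPSA + 0.139` and flags
#' compounds above `threshold` as permeable. This is a published-form
#' surrogate for proprietary ADMET predictors: it captures the dominant
#' lipophilicity/polar-surface-area trade-off, not a full pharmacokinetic
#' model.
#'
#' @param props data frame with columns `logp` and `tpsa` (Angstrom squared).
#' @param threshold minimum logBB for a pass (default -1.0).
#' @return a tibble with `logbb` and logical `bbb_pass`.
#' @export
#' @examples
#' bbb_permeable(data.frame(logp = 2, tpsa = 50))
bbb_permeable <- function(props, threshold = -1.0) {
  props <- as_tibble(props)
  if (!"tpsa" %in% names(props) || anyNA(props$tpsa)) {
    abort("`tpsa` is required for the logBB surrogate; supply or compute topological polar surface area first")
  }
  logbb <- 0.152 * props$logp - 0.0148 * props$tpsa + 0.139
  tibble(logbb = logbb, bbb_pass = logbb >= threshold)
}

#' Drug-likeness and permeability filter cascade
#'
#' Applies the rule-of-five filter and then the blood-brain-barrier
#' surrogate to a set of pharmacophore-screen survivors, recording the
#' count remaining after each stage. Counts are monotone non-increasing by
#' construction.
#'
#' @param hits compound tibble (must carry `compound_id`, `mw`, `logp`,
#'   `hbd`, `hba`, `rotb`, `tpsa`).
#' @param config a [pipeline_config()]; supplies `ro5_min_satisfied` and
#'   `logbb_threshold`.
#' @param group optional label for the screening group (target x site).
#' @return a `cascade_result`: list with `group`, `n_pharmacophore_hits`,
#'   `n_druglike`, `n_bbb_permeable`, `surviving_ids` (sorted), and
#'   `compounds` (the surviving rows).
#' @export
filter_cascade <- function(hits, config = pipeline_config(), group = NA_character_) {
  ro5 <- lipinski_score(hits, min_satisfied = config$ro5_min_satisfied)
  druglike <- hits[ro5$ro5_pass, , drop = FALSE]
  bbb <- if (nrow(druglike) > 0) {
    bbb_permeable(druglike, threshold = config$logbb_threshold)
  } else {
    tibble(logbb = double(), bbb_pass = logical())
  }
  surviving <- druglike[bbb$bbb_pass, , drop = FALSE]
  structure(list(
    group = group,
    n_pharmacophore_hits = nrow(hits),
    n_druglike = nrow(druglike),
    n_bbb_permeable = nrow(surviving),
    surviving_ids = sort(surviving$compound_id),
    compounds = surviving
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result>%s %d pharmacophore hits -> %d drug-like -> %d BBB-permeable\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$n_pharmacophore_hits, x$n_druglike, x$n_bbb_permeable))
  invisible(x)
}
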