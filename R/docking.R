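#' Paired-atom RMSD between two ligand poses
#'
#' Root-mean-square deviation over atoms paired by index:
#' `sqrt(mean(|a_i - b_i|^2))`. By default no superposition is applied —
#' the re-docking check compares poses in the common receptor frame. With
#' `superpose = TRUE` the optimal rigid (Kabsch) superposition is applied
#' first, for poses recorded in different frames.
#'
#' @param pose_a,pose_b `pose_coordinates` with equal atom counts.
#' @param superpose apply optimal rigid superposition first. Default `FALSE`.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' a <- pose_coordinates(c("C", "N"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' b <- pose_coordinates(c("C", "N"), rbind(c(1, 0, 0), c(2, 0, 0)))
#' pose_rmsd(a, b)  # 1.0
pose_rmsd <- function(pose_a, pose_b, superpose = FALSE) {
  a <- pose_a$coords
  b <- pose_b$coords
  if (nrow(a) != nrow(b)) {
    abort(sprintf("atom count mismatch: %d vs %d", nrow(a), nrow(b)))
  }
  if (superpose) {
    xa <- as.vector(t(a))
    xb <- as.vector(t(b))
    inds <- seq_along(xa)
    fitted <- bio3d::fit.xyz(fixed = xa, mobile = xb,
                             fixed.inds = inds, mobile.inds = inds)
    b <- matrix(as.numeric(fitted), ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Spearman rank correlation of experimental affinity versus docking score
#'
#' Ranks Ki ascending (the strongest binder, lowest Ki, is rank 1) and the
#' docking score descending (the best-scored pose is rank 1), then
#' correlates the two rank vectors. In the tie-free case the classical
#' formula `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))` is used; with ties,
#' average (fractional) ranks and the product-moment correlation of the
#' rank vectors.
#'
#' @param ki numeric vector of experimental affinities (nM).
#' @param scores numeric vector of docking total scores, same length.
#' @return a `spearman_result`: list with `rho`, `n`, `ki_ranks`,
#'   `score_ranks` (competition ranks, for reporting), `sum_d2` (tie-free
#'   case only), `tied` flag.
#' @export
#' @examples
#' b <- mglur_binders("mglur4")
#' spearman_rho(b$ki_nM, b$total_score)$rho  # 0.9286 to 4 decimals
spearman_rho <- function(ki, scores) {
  n <- length(ki)
  assert_that(n == length(scores), "`ki` and `scores` must have equal length")
  assert_that(n >= 2, "need at least two binders to correlate")
  assert_that(all(ki > 0), "Ki values must be positive")
  tied <- anyDuplicated(ki) > 0 || anyDuplicated(scores) > 0
  ki_rank <- competition_rank(ki, "ascending")
  score_rank <- competition_rank(scores, "descending")
  if (!tied) {
    d2 <- sum((ki_rank - score_rank)^2)
    rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  } else {
    r1 <- rank(ki)          # average ranks, ascending
    r2 <- rank(-scores)     # average ranks, descending score
    if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
      abort("rank correlation undefined: zero rank variance")
    }
    rho <- cor(r1, r2)
    d2 <- NA_real_
  }
  structure(list(rho = rho, n = n, ki_ranks = ki_rank,
                 score_ranks = score_rank, sum_d2 = d2, tied = tied),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("<spearman_result> n = %d, rho = %s%s\n", x$n,
              format_report_number(x$rho),
              if (x$tied) " (tied ranks)" else ""))
  invisible(x)
}

#' Validate a set of known binders against a docking model
#'
#' The two checks used to accept a docking setup: every known binder must
#' dock with a total score strictly above `min_score` (default 4), and,
#' when at least two experimental affinities are available, the Spearman
#' correlation between Ki rank and score rank is reported.
#'
#' @param binders tibble with `compound_id`, `ki_nM` (may be `NA`),
#'   `total_score`.
#' @param min_score score threshold, strict inequality (default 4.0).
#' @return a `validation_result`: list with `n_binders`,
#'   `all_docked_above_threshold`, `min_score`, and either `correlation`
#'   (a `spearman_result`) or `omitted_reason`.
#' @export
#' @examples
#' validate_binders(mglur_binders("mglur7"))
validate_binders <- function(binders, min_score = 4.0) {
  assert_that(nrow(binders) >= 1, "need at least one binder")
  ok <- all(binders$total_score > min_score)
  with_ki <- binders[!is.na(binders$ki_nM), , drop = FALSE]
  res <- list(n_binders = nrow(binders),
              all_docked_above_threshold = ok,
              min_score = min_score)
  if (nrow(with_ki) >= 2) {
    res$correlation <- spearman_rho(with_ki$ki_nM, with_ki$total_score)
  } else {
    res$omitted_reason <-
      sprintf("only %d binder(s) with affinity data; need 2", nrow(with_ki))
  }
  structure(res, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %d binders; all scores > %.1f: %s\n",
              x$n_binders, x$min_score, x$all_docked_above_threshold))
  if (!is.null(x$correlation)) {
    cat(sprintf("  Ki-rank vs score correlation: %s\n",
                format_report_number(x$correlation$rho)))
  } else {
    cat(sprintf("  correlation omitted: %s\n", x$omitted_reason))
  }
  invisible(x)
}

#' Bundled known-binder tables
#'
#' Experimental affinities (Ki, nM) and docking total scores for the known
#' binders of three group-III mGluR subtypes, used as the package's worked
#' example for docking validation. The mGluR4 table has seven binders, the
#' mGluR7 table three, and the mGluR8 table nine.
#'
#' @param target one of `"mglur4"`, `"mglur7"`, `"mglur8"`.
#' @return a binder tibble with `compound_id`, `ki_nM`, `total_score`.
#' @export
#' @examples
#' spearman_rho(mglur_binders("mglur8")$ki_nM, mglur_binders("mglur8")$total_score)
mglur_binders <- function(target = c("mglur4", "mglur7", "mglur8")) {
  target <- match.arg(target)
  read_table(system.file("extdata", paste0("binders_", target, ".tsv"),
                         package = "tcmflavor"), "binders")
}
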