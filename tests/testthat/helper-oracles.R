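# Independent brute-force oracles used to check the package's algorithms.
# These are written from the definitions, not from the package code paths.

# Pareto rank: count of strict dominators, computed with matrix comparisons
oracle_pareto <- function(models, objectives) {
  m <- sapply(names(objectives), function(p) {
    v <- models[[p]]
    if (objectives[[p]] == "minimize") -v else v
  })
  m <- matrix(m, nrow = nrow(models))
  sapply(seq_len(nrow(m)), function(i) {
    sum(sapply(seq_len(nrow(m)), function(j) {
      j != i && all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])
    }))
  })
}

# competition rank via sorting
oracle_competition_rank <- function(values, descending = FALSE) {
  v <- if (descending) -values else values
  rank(v, ties.method = "min")
}

# independent re-ranking + summation for model selection
oracle_sum_ranking <- function(stats, include_nhits = FALSE) {
  sums <- rank(stats$energy, ties.method = "min") +
    rank(-stats$specificity, ties.method = "min") +
    rank(-stats$sterics, ties.method = "min") +
    rank(-stats$hbond, ties.method = "min") +
    rank(-stats$mol_qry, ties.method = "min")
  if (include_nhits) sums <- sums + rank(-stats$n_hits, ties.method = "min")
  names(sums) <- stats$model_id
  sums
}

oracle_optimal_model <- function(stats, include_nhits = FALSE) {
  sums <- oracle_sum_ranking(stats, include_nhits)
  cand <- names(sums)[sums == min(sums)]
  if (length(cand) > 1) {
    e <- stats$energy[match(cand, stats$model_id)]
    cand <- cand[order(e, cand)]
  }
  cand[1]
}

# exhaustive pharmacophore matcher: enumerate every injective same-kind
# assignment (each model feature assigned to a compound feature or skipped),
# keep the feasible one of largest size, breaking ties by lowest mean
# squared pairwise discrepancy
oracle_match <- function(compound_features, model, min_matched) {
  feats <- model$features
  nm <- nrow(feats)
  dmod <- as.matrix(dist(as.matrix(feats[, c("x", "y", "z")])))
  cc <- as.matrix(compound_features[, c("x", "y", "z")])
  dcmp <- if (nrow(cc) > 1) as.matrix(dist(cc)) else matrix(0, nrow(cc), nrow(cc))
  tol <- feats$tolerance
  choices <- lapply(seq_len(nm), function(i) {
    c(NA_integer_, which(compound_features$kind == feats$kind[i]))
  })
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  best_size <- -1L
  best_msd <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    used <- asg[!is.na(asg)]
    if (anyDuplicated(used)) next
    ok <- TRUE
    ss <- 0
    np <- 0L
    idx <- which(!is.na(asg))
    if (length(idx) >= 2) {
      for (a in seq_along(idx)) {
        for (b in seq_len(a - 1)) {
          i <- idx[a]; k <- idx[b]
          disc <- abs(dmod[i, k] - dcmp[asg[i], asg[k]])
          if (disc > tol[i] + tol[k]) { ok <- FALSE; break }
          ss <- ss + disc^2
          np <- np + 1L
        }
        if (!ok) break
      }
    }
    if (!ok) next
    size <- length(idx)
    msd <- if (np > 0) ss / np else 0
    if (size > best_size || (size == best_size && msd < best_msd)) {
      best_size <- size
      best_msd <- msd
    }
  }
  list(matched = best_size >= min_matched,
       n_features_matched = max(best_size, 0L),
       rms_deviation = sqrt(best_msd))
}

# random model-statistics table for property tests
random_stats_table <- function(n) {
  tibble::tibble(
    model_id = sprintf("m%02d", seq_len(n)),
    specificity = round(runif(n, 3, 4), 2),
    n_hits = 6L,
    pareto = 0L,
    energy = round(runif(n, 1, 20), 1),
    sterics = round(runif(n, 180, 210), 1),
    hbond = round(runif(n, 95, 110), 1),
    mol_qry = round(runif(n, 0.5, 3), 1)
  )
}

random_pose <- function(n) {
  pose_coordinates(rep("C", n), matrix(rnorm(3 * n, sd = 2), ncol = 3))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# minimal TCM catalog builder for hand-constructed cases
make_tcms <- function(flavors, effects = NULL) {
  n <- length(flavors)
  if (is.null(effects)) effects <- replicate(n, character(), simplify = FALSE)
  tibble::tibble(tcm_id = sprintf("T%03d", seq_len(n)),
                 name = sprintf("herb-%03d", seq_len(n)),
                 flavors = flavors, effects = effects)
}
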