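objectives_default <- c(specificity = "maximize", energy = "minimize",
                        sterics = "maximize", hbond = "maximize",
                        mol_qry = "maximize")

test_that("pareto_rank matches exhaustive pairwise dominance on random tables", {
  expect_equal(pareto_rank(random_stats_table(1))$pareto_rank, 0L)

  # two identical models: neither strictly dominates
  s <- random_stats_table(2)
  s[2, -1] <- s[1, -1]
  expect_equal(pareto_rank(s)$pareto_rank, c(0L, 0L))

  set.seed(42)
  for (rep in 1:20) {
    s <- random_stats_table(sample(2:8, 1))
    got <- pareto_rank(s, objectives_default)
    expect_equal(got$pareto_rank, oracle_pareto(s, objectives_default))
  }
  expect_error(pareto_rank(random_stats_table(3), c(bogus = "maximize")),
               "unknown parameter")
})

test_that("candidate pre-screen keeps pareto-0 models with matching hit counts", {
  stats <- mglur_model_stats()
  expect_equal(nrow(screen_model_candidates(stats, n_training = 6)), 9)

  one <- stats[1, ]
  one$n_hits <- 5L
  expect_equal(nrow(screen_model_candidates(one, n_training = 6)), 0)
  expect_equal(nrow(screen_model_candidates(one, n_training = 6, slack = 1)), 1)
  one$n_hits <- 6L
  one$pareto <- 1L
  expect_equal(nrow(screen_model_candidates(one, n_training = 6)), 0)
})

test_that("parameter ranks follow the stated directions with competition ties", {
  stats <- mglur_model_stats()
  ranks <- assign_parameter_ranks(stats)

  # energy ascending: lowest energy (3.73) is rank 1, highest (16.61) rank 9
  expect_equal(ranks$energy[ranks$model_id == "model 15"], 1L)
  expect_equal(ranks$energy[ranks$model_id == "model 13"], 9L)
  # sterics descending with a tie: 203.30 rank 1; 203.10 twice, both rank 2
  expect_equal(ranks$sterics[ranks$model_id == "model 13"], 1L)
  expect_equal(ranks$sterics[ranks$model_id %in% c("model 01", "model 03")],
               c(2L, 2L))

  # all-tied parameter: everyone rank 1
  tied <- stats
  tied$hbond <- 100
  expect_equal(assign_parameter_ranks(tied)$hbond, rep(1L, 9))

  # tie-free parameter ranks are a permutation of 1..n
  set.seed(9)
  s <- random_stats_table(7)
  s$energy <- sample(seq(1, 20, length.out = 7))  # distinct
  expect_setequal(assign_parameter_ranks(s)$energy, 1:7)
})

test_that("summed ranks agree with an independent re-ranking oracle", {
  stats <- mglur_model_stats()
  sel <- sum_ranking(stats)
  oracle <- oracle_sum_ranking(stats)
  got <- setNames(sel$sum_ranking$sum_ranking, sel$sum_ranking$model_id)
  expect_equal(got[names(oracle)], oracle)
  expect_equal(got[["model 01"]], 13L)
  expect_equal(got[["model 13"]], 28L)
  expect_equal(sel$optimal_model, "model 01")
  expect_false(sel$tie_broken)

  # sum is the sum of that model's parameter ranks
  r <- sel$ranks[sel$ranks$model_id == "model 01", ]
  expect_equal(got[["model 01"]],
               r$specificity + r$energy + r$sterics + r$hbond + r$mol_qry)

  # single candidate: every rank 1, sum = number of parameters
  single <- sum_ranking(stats[1, ])
  expect_equal(single$sum_ranking$sum_ranking, 5L)
  expect_equal(sum_ranking(stats[1, ], include_nhits = TRUE)$sum_ranking$sum_ranking, 6L)

  set.seed(1234)
  for (rep in 1:200) {
    s <- random_stats_table(sample(2:9, 1))
    sel <- sum_ranking(s)
    o <- oracle_sum_ranking(s)
    got <- setNames(sel$sum_ranking$sum_ranking, sel$sum_ranking$model_id)
    expect_equal(got[names(o)], o)
    expect_equal(sel$optimal_model, oracle_optimal_model(s))
  }
})

test_that("selection is invariant to candidate order and monotone in energy", {
  stats <- mglur_model_stats()
  set.seed(5)
  for (rep in 1:5) {
    shuf <- stats[sample.int(nrow(stats)), ]
    sel_a <- sum_ranking(stats)
    sel_b <- sum_ranking(shuf)
    expect_equal(sel_b$optimal_model, sel_a$optimal_model)
    expect_equal(dplyr::arrange(sel_b$sum_ranking, model_id),
                 dplyr::arrange(sel_a$sum_ranking, model_id))
  }

  # decreasing one model's energy never worsens its energy rank
  set.seed(6)
  s <- random_stats_table(6)
  before <- assign_parameter_ranks(s)$energy[3]
  s$energy[3] <- s$energy[3] - 5
  after <- assign_parameter_ranks(s)$energy[3]
  expect_lte(after, before)
})

test_that("winner ties are broken by lower energy and flagged", {
  s <- random_stats_table(2)
  s[2, c("specificity", "sterics", "hbond", "mol_qry")] <-
    s[1, c("specificity", "sterics", "hbond", "mol_qry")]
  s$energy <- c(10, 2)  # model 2 wins energy; both sums tie at 1+2+... pattern?
  sel <- sum_ranking(s)
  # with two models and four tied parameters, sums are 4+rank(energy): 6 vs 5
  expect_equal(sel$optimal_model, "m02")
  # force an exact tie: identical rows
  s[2, -1] <- s[1, -1]
  sel <- sum_ranking(s)
  expect_true(sel$tie_broken)
  expect_equal(sel$optimal_model, "m01")  # lexicographic fallback
})

test_that("feature matching agrees with exhaustive assignment enumeration", {
  model <- example_pharmacophore("orthosteric")

  # compound exactly at the model centers: full match, zero deviation
  exact <- model$features[, c("kind", "x", "y", "z")]
  res <- match_pharmacophore(exact, model, min_matched = "all")
  expect_true(res$matched)
  expect_equal(res$n_features_matched, 4L)
  expect_equal(res$rms_deviation, 0)

  # compound lacking a required kind cannot fully match
  no_nc <- exact[exact$kind != "NC", ]
  expect_false(match_pharmacophore(no_nc, model, min_matched = "all")$matched)

  expect_error(match_pharmacophore(exact, model, min_matched = 9), "exceeds")

  # random instances vs the brute-force oracle
  set.seed(77)
  for (rep in 1:15) {
    nm <- sample(3:4, 1)
    mdl <- pharmacophore_model("rnd", tibble::tibble(
      kind = sample(c("NP", "HY", "NC", "AA"), nm, replace = TRUE),
      x = runif(nm, -4, 4), y = runif(nm, -4, 4), z = runif(nm, -4, 4),
      tolerance = runif(nm, 0.5, 1.5)
    ))
    nc <- sample(4:6, 1)
    cmp <- tibble::tibble(
      kind = sample(c("NP", "HY", "NC", "AA"), nc, replace = TRUE),
      x = runif(nc, -4, 4), y = runif(nc, -4, 4), z = runif(nc, -4, 4)
    )
    min_matched <- sample(seq_len(nm), 1)
    got <- match_pharmacophore(cmp, mdl, min_matched = min_matched)
    want <- oracle_match(cmp, mdl, min_matched)
    expect_equal(got$matched, want$matched)
    expect_equal(got$n_features_matched, want$n_features_matched)
    expect_equal(got$rms_deviation, want$rms_deviation, tolerance = 1e-10)
  }
})

test_that("jittering a model within half its tolerances always matches fully", {
  set.seed(99)
  for (site in c("orthosteric", "allosteric")) {
    model <- example_pharmacophore(site)
    tf <- model$features
    for (rep in 1:20) {
      jit <- matrix(runif(3 * nrow(tf), -1, 1), ncol = 3)
      jit <- jit / sqrt(rowSums(jit^2)) *
        runif(nrow(tf), 0, min(tf$tolerance) / 2)
      cmp <- tibble::tibble(kind = tf$kind, x = tf$x + jit[, 1],
                            y = tf$y + jit[, 2], z = tf$z + jit[, 3])
      expect_true(match_pharmacophore(cmp, model, min_matched = "all")$matched)
    }
  }
})
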