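test_that("tracing dedups medicines by id and is idempotent", {
  catalog <- make_tcms(list("sweet", c("sweet", "bitter"), "salty"))
  compounds <- tibble::tibble(
    compound_id = c("C1", "C2", "C3"),
    tcm_ids = list("T001", "T001", c("T002", "T001"))
  )
  got <- trace_tcms(c("C1", "C2"), compounds, catalog)
  expect_equal(got$tcm_id, "T001")

  expect_equal(nrow(trace_tcms(character(), compounds, catalog)), 0)

  got2 <- trace_tcms(c("C1", "C2", "C3"), compounds, catalog)
  expect_equal(got2$tcm_id, c("T001", "T002"))

  expect_error(trace_tcms("C9", compounds, catalog), "C9")
  bad <- compounds
  bad$tcm_ids[[1]] <- "T999"
  expect_error(trace_tcms("C1", bad, catalog), "T999")

  # idempotence: tracing the traced set through identity compounds
  id_compounds <- tibble::tibble(compound_id = got2$tcm_id,
                                 tcm_ids = as.list(got2$tcm_id))
  expect_equal(trace_tcms(got2$tcm_id, id_compounds, catalog), got2)
})

test_that("trace matches a set-union oracle on a synthetic library", {
  spec <- synthetic_spec(n_tcms = 40, n_compounds = 80, seed = 17)
  catalog <- generate_tcm_catalog(spec)
  lib <- generate_compound_library(spec, catalog)
  hits <- lib$compound_id[seq(1, 80, by = 2)]
  got <- trace_tcms(hits, lib, catalog)
  want <- sort(Reduce(union, lib$tcm_ids[match(hits, lib$compound_id)]))
  expect_equal(got$tcm_id, want)
})

test_that("flavor frequencies count each medicine once per carried flavor", {
  one <- make_tcms(list("sweet"))
  f <- flavor_frequency(one)
  expect_equal(f$count[f$flavor == "sweet"], 1L)
  expect_equal(f$fraction[f$flavor == "sweet"], 1.0)
  expect_equal(sum(f$count), 1L)

  two <- make_tcms(list("sweet", c("sweet", "bitter")))
  f <- flavor_frequency(two)
  expect_equal(f$count[f$flavor == "sweet"], 2L)
  expect_equal(f$fraction[f$flavor == "sweet"], 1.0)
  expect_equal(f$count[f$flavor == "bitter"], 1L)
  expect_equal(f$fraction[f$flavor == "bitter"], 0.5)

  expect_error(flavor_frequency(one[0, ]), "at least one")

  # counting oracle on 200 synthetic medicines; multi-flavor sum property
  catalog <- generate_tcm_catalog(synthetic_spec(n_tcms = 200, seed = 23))
  f <- flavor_frequency(catalog)
  for (fl in f$flavor) {
    expect_equal(f$count[f$flavor == fl],
                 sum(sapply(catalog$flavors, function(v) fl %in% v)))
  }
  expect_gte(sum(f$count), nrow(catalog))
})

test_that("effect ranking sorts by count then label and truncates", {
  tcms <- make_tcms(
    rep(list("sweet"), 4),
    list(c("Zhi Tong"), c("Zhi Tong", "Jie Du"), c("Jie Du"), c("Huo Xue"))
  )
  r <- effect_frequency(tcms, top_k = 2)
  expect_equal(r$effect, c("Jie Du", "Zhi Tong"))  # tie at 2, label order
  expect_equal(r$count, c(2L, 2L))
  expect_equal(effect_frequency(make_tcms(list("sour"))),
               tibble::tibble(effect = character(), count = integer()))
})

test_that("enrichment scores and p-values behave under null and planted signal", {
  catalog <- generate_tcm_catalog(synthetic_spec(n_tcms = 100, seed = 41))
  # group == background: score exactly zero
  e <- flavor_enrichment(catalog, catalog, "sweet", n_perm = 50, seed = 1)
  expect_equal(e$score, 0)

  # n_perm = 1 floor
  half <- catalog[1:50, ]
  e1 <- flavor_enrichment(half, catalog, "sweet", n_perm = 1, seed = 2)
  expect_true(e1$p_value %in% c(0.5, 1.0))

  # bit-for-bit reproducibility under a fixed seed
  ea <- flavor_enrichment(half, catalog, "bitter", n_perm = 500, seed = 7)
  eb <- flavor_enrichment(half, catalog, "bitter", n_perm = 500, seed = 7)
  expect_identical(ea, eb)
  expect_error(flavor_enrichment(catalog, half, "sweet"), "larger")

  # null: random groups give non-extreme p-values on average
  set.seed(55)
  ps <- replicate(20, {
    grp <- catalog[sample.int(100, 40), ]
    flavor_enrichment(grp, catalog, "sweet", n_perm = 200,
                      seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)

  # planted enrichment: sweet fraction 0.8 in group vs 0.3 in background
  planted_bg <- make_tcms(c(
    replicate(18, "sweet", simplify = FALSE),
    replicate(42, "bitter", simplify = FALSE)
  ))
  grp <- make_tcms(c(
    replicate(48, "sweet", simplify = FALSE),
    replicate(12, "bitter", simplify = FALSE)
  ))
  background <- dplyr::bind_rows(planted_bg, grp)
  background$tcm_id <- sprintf("T%03d", seq_len(nrow(background)))
  e <- flavor_enrichment(grp, background, "sweet", n_perm = 2000, seed = 3)
  expect_gt(e$score, 0.2)
  expect_lt(e$p_value, 0.01)
})

test_that("the tripartite network links each group to its flavors and functions", {
  tcms <- make_tcms(
    list("sweet", "sweet", c("sweet", "bitter")),
    list(c("Zhi Tong", "Huo Xue"), c("Zhi Tong", "Xiao Zhong"), "Zhi Tong")
  )
  compounds <- tibble::tibble(compound_id = c("C1", "C2"),
                              tcm_ids = list(c("T001", "T002"), "T003"))
  res <- associate_flavors(c("C1", "C2"), compounds, tcms,
                           group = "g1", n_perm = 20, seed = 1)
  edges <- build_flavor_network(list(res))
  fl <- edges[edges$to_type == "flavor", ]
  fn <- edges[edges$to_type == "function", ]
  expect_equal(fl$to, "sweet")
  expect_equal(fl$weight, 1.0)
  expect_equal(nrow(fn), 3)
  expect_equal(fn$to[1], "Zhi Tong")
  expect_equal(fn$weight[1], 3)

  expect_equal(nrow(build_flavor_network(list())), 0)
  expect_error(build_flavor_network(list(res, res)), "duplicate")

  # six synthetic groups: node/edge counts equal an independent recount
  spec <- synthetic_spec(n_tcms = 60, n_compounds = 120, seed = 61)
  catalog <- generate_tcm_catalog(spec)
  lib <- generate_compound_library(spec, catalog)
  groups <- paste0("grp", 1:6)
  results <- lapply(1:6, function(i) {
    ids <- lib$compound_id[seq(i, 120, by = 6)]
    associate_flavors(ids, lib, catalog, group = groups[i],
                      n_perm = 20, seed = i)
  })
  edges <- build_flavor_network(results)
  expect_equal(sort(unique(edges$from)), sort(groups))
  for (r in results) {
    mine <- edges[edges$from == r$group, ]
    expect_equal(sum(mine$to_type == "flavor"), 1)
    expect_equal(sum(mine$to_type == "function"), nrow(r$effect_ranking))
  }

  # serialization: JSON node-link and TSV edge list
  dir <- withr::local_tempdir()
  nl <- write_flavor_network(edges, file.path(dir, "n.json"),
                             file.path(dir, "n.tsv"))
  expect_equal(nrow(nl$nodes), length(unique(c(edges$from, edges$to))))
  expect_true(file.exists(file.path(dir, "n.json")))
  back <- readr::read_tsv(file.path(dir, "n.tsv"), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(edges))
})

test_that("planted site-flavor associations are recovered as top flavors", {
  spec <- synthetic_spec(seed = 71)
  catalog <- generate_tcm_catalog(spec)
  lib <- generate_compound_library(spec, catalog)
  for (site in c("orthosteric", "allosteric")) {
    ids <- lib$compound_id[lib$latent_site == site]
    res <- associate_flavors(ids, lib, catalog, group = site,
                             n_perm = 200, seed = 71)
    planted <- spec$planted[[site]]$flavor
    expect_equal(res$flavor_frequencies$flavor[
      which.max(res$flavor_frequencies$count)], planted)
    enr <- res$flavor_frequencies[res$flavor_frequencies$flavor == planted, ]
    expect_lt(enr$p_value, 0.05)
  }
})
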