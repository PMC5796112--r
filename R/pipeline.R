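#' Run the full screening-to-association pipeline
#'
#' Executes the six stages in order — model selection, pharmacophore
#' screening, drug-likeness/permeability filtering, docking validation,
#' flavor/effect association, and network export — writing each stage's
#' output under `out_dir` before the next stage starts, and returning a
#' run manifest. With `inputs = "simulate"` the synthetic generators supply
#' the compound library and medicine catalog; otherwise `inputs` is a named
#' list of file paths (`compounds`, `tcm`, optionally `model_stats`,
#' `n_training`).
#'
#' @param config a [pipeline_config()].
#' @param inputs `"simulate"` or a named list of paths.
#' @param out_dir output directory (created if needed).
#' @param spec synthetic-data conditions used when simulating
#'   (default [synthetic_spec()] with the config's seed).
#' @param n_training training-set size for model pre-screening (default 6,
#'   matching the bundled model-statistics example).
#' @return a `run_manifest` list: config snapshot, seed, per-stage status
#'   and output paths, timestamps.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         inputs = "simulate",
                         out_dir = tempfile("tcmflavor_run_"),
                         spec = NULL,
                         n_training = 6L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "tcmflavor",
    version = as.character(utils::packageVersion("tcmflavor")),
    seed = config$seed,
    config = unclass(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  stage_paths <- character()
  record <- function(stage, status, path = NA_character_) {
    manifest$stages[[stage]] <<- list(status = status, output = path)
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) {
      record(stage, "failed")
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      write_report(manifest, file.path(out_dir, "manifest.json"), "json")
      abort(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)))
    })
    res
  }

  # --- inputs -------------------------------------------------------------
  simulate <- identical(inputs, "simulate")
  if (simulate) {
    if (is.null(spec)) spec <- synthetic_spec(seed = config$seed)
    catalog <- generate_tcm_catalog(spec)
    compounds <- generate_compound_library(spec, catalog)
    write_table(catalog, file.path(out_dir, "tcm_catalog.tsv"))
    write_table(compounds, file.path(out_dir, "compound_library.tsv"))
    model_stats <- mglur_model_stats()
  } else {
    assert_that(is.list(inputs) && all(c("compounds", "tcm") %in% names(inputs)),
                "`inputs` must be \"simulate\" or a list with $compounds and $tcm")
    catalog <- read_table(inputs$tcm, "tcm")
    compounds <- read_table(inputs$compounds, "compounds")
    model_stats <- if (!is.null(inputs$model_stats)) {
      read_table(inputs$model_stats, "model_stats")
    } else {
      mglur_model_stats()
    }
    if (!is.null(inputs$n_training)) n_training <- inputs$n_training
  }

  # --- stage 1: model selection -------------------------------------------
  selection <- run_stage("select_model", function() {
    cand <- screen_model_candidates(model_stats, n_training = n_training)
    assert_that(nrow(cand) >= 1, "no model candidates survive pre-screening")
    sum_ranking(cand, include_nhits = config$rank_include_nhits)
  })
  p <- file.path(out_dir, "model_selection.json")
  write_report(list(optimal_model = selection$optimal_model,
                    tie_broken = selection$tie_broken,
                    sum_ranking = selection$sum_ranking), p, "json")
  record("select_model", "ok", p)

  # --- stage 2: pharmacophore screening (one group per site) --------------
  templates <- list(orthosteric = example_pharmacophore("orthosteric"),
                    allosteric = example_pharmacophore("allosteric"))
  screened <- run_stage("screen", function() {
    lapply(templates, function(tmpl) {
      hit <- screen_library(compounds, tmpl,
                            min_matched = config$min_matched_features)
      hit[hit$matched, , drop = FALSE]
    })
  })
  p <- file.path(out_dir, "screen_counts.json")
  write_report(lapply(screened, nrow), p, "json")
  record("screen", "ok", p)

  # --- stage 3: drug-likeness / BBB filter cascade ------------------------
  cascades <- run_stage("filter", function() {
    lapply(names(screened), function(site) {
      filter_cascade(screened[[site]], config = config, group = site)
    })
  })
  names(cascades) <- names(screened)
  cascade_tbl <- purrr::map_dfr(cascades, function(cc) {
    tibble(group = cc$group,
           n_pharmacophore_hits = cc$n_pharmacophore_hits,
           n_druglike = cc$n_druglike,
           n_bbb_permeable = cc$n_bbb_permeable)
  })
  p <- file.path(out_dir, "filter_cascade.tsv")
  write_report(cascade_tbl, p, "tsv")
  record("filter", "ok", p)

  # --- stage 4: docking validation ----------------------------------------
  validation <- run_stage("validate_docking", function() {
    targets <- c("mglur4", "mglur7", "mglur8")
    vals <- lapply(targets, function(t) {
      validate_binders(mglur_binders(t), min_score = config$min_total_score)
    })
    names(vals) <- targets
    poses <- generate_pose_pair(20, 1.4946,
                                seed = derive_seed(config$seed, "redock"))
    vals$redock_rmsd <- pose_rmsd(poses[[1]], poses[[2]],
                                  superpose = config$superpose_before_rmsd)
    vals
  })
  val_tbl <- purrr::map_dfr(c("mglur4", "mglur7", "mglur8"), function(t) {
    v <- validation[[t]]
    tibble(target = t, n_binders = v$n_binders,
           all_above_threshold = v$all_docked_above_threshold,
           rho = if (!is.null(v$correlation)) v$correlation$rho else NA_real_)
  })
  p <- file.path(out_dir, "docking_validation.tsv")
  write_report(val_tbl, p, "tsv")
  record("validate_docking", "ok", p)

  # --- stage 5: flavor / effect association -------------------------------
  associations <- run_stage("associate", function() {
    lapply(names(cascades), function(site) {
      ids <- cascades[[site]]$surviving_ids
      assert_that(length(ids) >= 1,
                  sprintf("no surviving compounds for site '%s'", site))
      associate_flavors(ids, compounds, catalog, group = site,
                        n_perm = config$n_permutations, seed = config$seed)
    })
  })
  names(associations) <- names(cascades)
  for (site in names(associations)) {
    write_report(associations[[site]]$flavor_frequencies,
                 file.path(out_dir, paste0("flavors_", site, ".tsv")), "tsv")
  }
  record("associate", "ok", file.path(out_dir, "flavors_orthosteric.tsv"))

  # --- stage 6: network export --------------------------------------------
  network <- run_stage("network", function() {
    build_flavor_network(unname(associations))
  })
  write_flavor_network(network,
                       json_path = file.path(out_dir, "network.json"),
                       tsv_path = file.path(out_dir, "network_edges.tsv"))
  record("network", "ok", file.path(out_dir, "network.json"))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_report(manifest[setdiff(names(manifest), "results")],
               file.path(out_dir, "manifest.json"), "json")
  structure(c(manifest, list(results = list(
    selection = selection, screened = screened, cascades = cascades,
    validation = validation, associations = associations, network = network,
    out_dir = out_dir
  ))), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> tcmflavor %s, seed %d\n", x$version, x$seed))
  for (s in names(x$stages)) {
    cat(sprintf("  %-18s %s\n", s, x$stages[[s]]$status))
  }
  invisible(x)
}
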