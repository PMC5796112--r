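#' Trace surviving compounds back to their source medicines
#'
#' Collects the union of the hit compounds' TCM provenance and removes
#' duplicates (a medicine contributing several hit compounds is counted
#' once per screening group). The dedup key is `tcm_id`, so transliteration
#' variants of a name cannot double-count. Output is sorted by `tcm_id`.
#'
#' @param hit_compound_ids character vector of surviving compound ids.
#' @param compounds compound tibble with `compound_id` and `tcm_ids`
#'   list-column.
#' @param catalog TCM tibble with `tcm_id`, `name`, `flavors`, `effects`.
#' @return the catalog rows of the traced medicines, deduplicated.
#' @export
trace_tcms <- function(hit_compound_ids, compounds, catalog) {
  missing <- setdiff(hit_compound_ids, compounds$compound_id)
  assert_that(length(missing) == 0,
              paste0("unknown compound id(s): ", paste(missing, collapse = ", ")))
  idx <- match(hit_compound_ids, compounds$compound_id)
  ids <- sort(unique(unlist(compounds$tcm_ids[idx])))
  dangling <- setdiff(ids, catalog$tcm_id)
  assert_that(length(dangling) == 0,
              paste0("tcm_id(s) absent from catalog: ",
                     paste(dangling, collapse = ", ")))
  catalog[match(ids, catalog$tcm_id), , drop = FALSE]
}

#' Five-flavor frequency table
#'
#' Counts, for each of the five flavors, how many medicines carry it. A
#' medicine annotated with k flavors contributes once to each of those k
#' flavors; fractions are counts divided by the number of medicines, so
#' they need not sum to one.
#'
#' @param tcms TCM tibble with a `flavors` list-column.
#' @return a tibble with `flavor`, `count`, `fraction`, ordered sour,
#'   bitter, sweet, pungent, salty.
#' @export
#' @examples
#' cat <- tibble::tibble(tcm_id = c("T1", "T2"), name = c("a", "b"),
#'                       flavors = list("sweet", c("sweet", "bitter")),
#'                       effects = list(character(), character()))
#' flavor_frequency(cat)
flavor_frequency <- function(tcms) {
  assert_that(nrow(tcms) >= 1, "need at least one traced medicine")
  counts <- vapply(FLAVORS, function(fl) {
    sum(vapply(tcms$flavors, function(v) fl %in% v, logical(1)))
  }, integer(1))
  tibble(flavor = FLAVORS, count = unname(counts),
         fraction = unname(counts) / nrow(tcms))
}

#' Traditional-effect frequency ranking
#'
#' Tallies the traditional pharmacological effects across medicines,
#' sorts by count descending (ties broken by label), and keeps the top k —
#' the "most representative functions" of a screening group.
#'
#' @param tcms TCM tibble with an `effects` list-column.
#' @param top_k how many effects to keep (default 3).
#' @return a tibble with `effect` and `count`, at most `top_k` rows.
#' @export
effect_frequency <- function(tcms, top_k = 3L) {
  assert_that(top_k >= 1, "`top_k` must be >= 1")
  effects <- unlist(tcms$effects)
  if (length(effects) == 0) {
    return(tibble(effect = character(), count = integer()))
  }
  tab <- table(effects)
  out <- tibble(effect = names(tab), count = as.integer(tab))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$effect)
  utils::head(out, top_k)
}

#' Permutation test for flavor enrichment in a screening group
#'
#' Quantifies whether a group's traced medicines carry a flavor more often
#' than the full catalog does. The score is the difference of carriage
#' fractions (group minus background); the p-value is estimated by drawing
#' `n_perm` random groups of the same size from the background without
#' replacement: `p = (1 + #{score_perm >= score_obs}) / (n_perm + 1)`.
#'
#' @param group_tcms traced medicines of one group.
#' @param background the full catalog.
#' @param flavor one of the five flavors.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the test is bit-for-bit reproducible.
#' @return a tibble with `flavor`, `score`, `p_value`, `n_group`,
#'   `n_background`, `n_perm`.
#' @export
flavor_enrichment <- function(group_tcms, background, flavor,
                              n_perm = 10000L, seed = 0L) {
  assert_that(flavor %in% FLAVORS,
              paste0("`flavor` must be one of: ", paste(FLAVORS, collapse = ", ")))
  assert_that(n_perm >= 1, "`n_perm` must be >= 1")
  ng <- nrow(group_tcms)
  nb <- nrow(background)
  assert_that(ng <= nb, "group is larger than background")
  has_flavor <- function(tcms) {
    vapply(tcms$flavors, function(v) flavor %in% v, logical(1))
  }
  bg_carry <- has_flavor(background)
  obs <- mean(has_flavor(group_tcms)) - mean(bg_carry)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(seed, paste0("flavor_enrichment/", flavor)))
  perm_ge <- 0L
  for (i in seq_len(n_perm)) {
    draw <- sample.int(nb, ng)
    if (mean(bg_carry[draw]) - mean(bg_carry) >= obs) perm_ge <- perm_ge + 1L
  }
  tibble(flavor = flavor, score = obs,
         p_value = (1 + perm_ge) / (n_perm + 1),
         n_group = ng, n_background = nb, n_perm = as.integer(n_perm))
}

#' Full flavor/effect association analysis for one screening group
#'
#' Traces a group's surviving compounds to their medicines, computes the
#' flavor frequency table (with enrichment tests against the catalog), and
#' ranks the traditional effects.
#'
#' @param hit_compound_ids surviving compound ids of the group.
#' @param compounds compound tibble.
#' @param catalog full TCM catalog (also the enrichment background).
#' @param group label, e.g. `"mGluR I/orthosteric"`.
#' @param top_k effects to keep (default 3).
#' @param n_perm,seed enrichment test parameters (see [flavor_enrichment()]).
#' @return an `association_result`: list with `group`, `n_tcms`,
#'   `flavor_frequencies` (tibble incl. `score`, `p_value`), `top_flavors`,
#'   `effect_ranking`, `tcms`.
#' @export
associate_flavors <- function(hit_compound_ids, compounds, catalog,
                              group = NA_character_, top_k = 3L,
                              n_perm = 10000L, seed = 0L) {
  tcms <- trace_tcms(hit_compound_ids, compounds, catalog)
  assert_that(nrow(tcms) >= 1, "no medicines traced for this group")
  freq <- flavor_frequency(tcms)
  enr <- purrr::map(FLAVORS, function(fl) {
    flavor_enrichment(tcms, catalog, fl, n_perm = n_perm,
                      seed = derive_seed(seed, paste0("group/", group)))
  })
  enr <- dplyr::bind_rows(enr)
  freq <- dplyr::left_join(freq, enr[, c("flavor", "score", "p_value")],
                           by = "flavor")
  ord <- order(-freq$count, freq$flavor)
  structure(list(
    group = group,
    n_tcms = nrow(tcms),
    flavor_frequencies = freq,
    top_flavors = freq$flavor[ord][freq$count[ord] > 0],
    effect_ranking = effect_frequency(tcms, top_k = top_k),
    tcms = tcms
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result>%s %d medicines; top flavor(s): %s\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$n_tcms, paste(utils::head(x$top_flavors, 2), collapse = ", ")))
  print(x$flavor_frequencies, ...)
  invisible(x)
}

#' Target-flavor-function network
#'
#' Assembles the tripartite summary network: each screening group
#' (target x site) links to its top flavor(s) (edge weight = carriage
#' fraction) and to its top-ranked traditional effects (edge weight =
#' count).
#'
#' @param results list of `association_result` objects, one per group.
#' @param top_flavor_k flavor edges per group (default 1, the dominant
#'   flavor; ties on count are all kept when they tie for first).
#' @return a tibble of edges: `from` (group), `to`, `to_type`
#'   (`"flavor"`/`"function"`), `weight`.
#' @export
build_flavor_network <- function(results, top_flavor_k = 1L) {
  if (length(results) == 0) {
    return(tibble(from = character(), to = character(),
                  to_type = character(), weight = double()))
  }
  groups <- vapply(results, `[[`, character(1), "group")
  assert_that(anyDuplicated(groups) == 0,
              "duplicate group results are not allowed")
  purrr::map_dfr(results, function(r) {
    ff <- dplyr::arrange(r$flavor_frequencies, dplyr::desc(.data$count),
                         .data$flavor)
    fl <- utils::head(ff[ff$count > 0, , drop = FALSE], top_flavor_k)
    flavor_edges <- tibble(from = r$group, to = fl$flavor,
                           to_type = "flavor", weight = fl$fraction)
    fn <- r$effect_ranking
    function_edges <- tibble(from = r$group, to = fn$effect,
                             to_type = "function", weight = as.double(fn$count))
    dplyr::bind_rows(flavor_edges, function_edges)
  })
}

#' Write a flavor network to node-link JSON and a TSV edge list
#'
#' @param edges edge tibble from [build_flavor_network()].
#' @param json_path,tsv_path output files (either may be `NULL` to skip).
#' @return invisibly, the node-link list structure.
#' @export
write_flavor_network <- function(edges, json_path = NULL, tsv_path = NULL) {
  node_names <- unique(c(edges$from, edges$to))
  node_type <- ifelse(node_names %in% edges$from, "target-site",
                      edges$to_type[match(node_names, edges$to)])
  nodes <- tibble(id = node_names, type = node_type)
  links <- edges
  names(links)[names(links) == "from"] <- "source"
  names(links)[names(links) == "to"] <- "target"
  nl <- list(nodes = nodes, links = links)
  if (!is.null(json_path)) {
    jsonlite::write_json(nl, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) write_report(edges, tsv_path, "tsv")
  invisible(nl)
}
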