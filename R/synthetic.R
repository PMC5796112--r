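#' Specification for the synthetic TCM library generator
#'
#' Defines the study conditions emulated by the generators: catalog and
#' library sizes, the base carriage probability of each flavor, the planted
#' site-to-flavor associations, and the molecular-property distributions.
#' Defaults plant the sweet flavor on orthosteric-site binders and the
#' bitter flavor on allosteric-site binders with an enrichment delta of
#' 0.3, over base flavor probabilities loosely shaped like a pharmacopoeia
#' (bitter and sweet common, sour and salty rare).
#'
#' @param n_tcms number of medicines in the catalog (default 200).
#' @param n_compounds number of library compounds (default 500).
#' @param flavor_base_probs named probabilities of carrying each flavor.
#' @param planted named list `site -> list(flavor, delta)`; `delta` is the
#'   added probability that a hit compound of that site links to a
#'   flavor-carrying medicine.
#' @param site_probs probabilities that a compound is a latent orthosteric
#'   hit, allosteric hit, or neither.
#' @param property_distributions location/scale parameters for MW
#'   (lognormal), logP (normal), HBD/HBA/RotB (Poisson) and TPSA (gamma).
#' @param seed master seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tcms = 200L,
                           n_compounds = 500L,
                           flavor_base_probs = c(sour = 0.12, bitter = 0.40,
                                                 sweet = 0.35, pungent = 0.30,
                                                 salty = 0.08),
                           planted = list(
                             orthosteric = list(flavor = "sweet", delta = 0.3),
                             allosteric  = list(flavor = "bitter", delta = 0.3)
                           ),
                           site_probs = c(orthosteric = 0.25,
                                          allosteric = 0.25, none = 0.50),
                           property_distributions = list(
                             mw = list(meanlog = log(350), sdlog = 0.35),
                             logp = list(mean = 2.5, sd = 1.5),
                             hbd = list(lambda = 2),
                             hba = list(lambda = 5),
                             rotb = list(lambda = 5),
                             tpsa = list(shape = 4, scale = 20)
                           ),
                           seed = 0L) {
  assert_that(all(flavor_base_probs >= 0 & flavor_base_probs <= 1),
              "flavor probabilities must lie in [0, 1]")
  assert_that(setequal(names(flavor_base_probs), FLAVORS),
              "flavor_base_probs must name the five flavors")
  for (s in names(planted)) {
    p <- planted[[s]]
    assert_that(p$flavor %in% FLAVORS, "planted flavor must be one of the five")
    assert_that(p$delta >= 0 && p$delta <= 1, "planted delta must lie in [0, 1]")
  }
  structure(list(n_tcms = as.integer(n_tcms),
                 n_compounds = as.integer(n_compounds),
                 flavor_base_probs = flavor_base_probs,
                 planted = planted,
                 site_probs = site_probs,
                 property_distributions = property_distributions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic TCM catalog
#'
#' Each medicine carries each flavor independently with its base
#' probability (at least one flavor is forced, drawn proportionally to the
#' base probabilities), and a small set of traditional effects from the
#' controlled vocabulary. Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a TCM tibble: `tcm_id`, `name`, `flavors`, `effects`.
#' @export
generate_tcm_catalog <- function(spec) {
  probs <- spec$flavor_base_probs[FLAVORS]
  assert_that(sum(probs) > 0, "at least one flavor probability must be positive")
  with_stream(spec$seed, "tcm_catalog", {
    n <- spec$n_tcms
    flavors <- vector("list", n)
    effects <- vector("list", n)
    for (i in seq_len(n)) {
      carry <- FLAVORS[runif(5) < probs]
      if (length(carry) == 0) {
        carry <- sample(FLAVORS, 1, prob = probs / sum(probs))
      }
      flavors[[i]] <- carry
      k <- min(rpois(1, 2), length(EFFECTS))
      effects[[i]] <- if (k > 0) sort(sample(EFFECTS, k)) else character()
    }
    tibble(tcm_id = sprintf("TCM%04d", seq_len(n)),
           name = sprintf("herb-%04d", seq_len(n)),
           flavors = flavors, effects = effects)
  })
}

#' The package's example pharmacophore templates
#'
#' Four-feature queries in the style of mGluR site models: the orthosteric
#' template has one positive nitrogen, one hydrophobe and two negative
#' centers (the zwitterionic glutamate motif); the allosteric template has
#' one acceptor atom, two hydrophobes and one aromatic ring (a typical
#' 7TMD modulator motif). Tolerance spheres are 1 Angstrom.
#'
#' @param site `"orthosteric"` or `"allosteric"`.
#' @return a [pharmacophore_model()].
#' @export
example_pharmacophore <- function(site = c("orthosteric", "allosteric")) {
  site <- match.arg(site)
  if (site == "orthosteric") {
    pharmacophore_model("ortho-4pt", tibble(
      kind = c("NP", "HY", "NC", "NC"),
      x = c(0.0, 3.2, -1.8, 1.5),
      y = c(0.0, 1.1, 2.4, -2.2),
      z = c(0.0, -0.8, 0.6, 1.9),
      tolerance = 1.0
    ))
  } else {
    pharmacophore_model("allo-4pt", tibble(
      kind = c("AA", "HY", "HY", "AR"),
      x = c(0.0, 2.8, -2.5, 0.9),
      y = c(0.0, -1.6, 1.2, 3.0),
      z = c(0.0, 1.4, -1.1, 0.7),
      tolerance = 1.0
    ))
  }
}

#' Generate a synthetic compound library with TCM provenance
#'
#' Each compound receives molecular properties from the spec's
#' distributions, one to three parent medicines, a latent site label, and
#' 3D feature points. Compounds that are latent hits of a site link to
#' medicines carrying that site's planted flavor with probability
#' `base carriage + delta`, and their feature points are that site's
#' template features jittered within half the tolerance (so they always
#' match the template). Non-hit compounds link uniformly and get random
#' feature points.
#'
#' @param spec a [synthetic_spec()].
#' @param catalog catalog from [generate_tcm_catalog()].
#' @param templates named list of [pharmacophore_model()]s used for hit
#'   construction, one per site (defaults to [example_pharmacophore()] for
#'   each site).
#' @return a compound tibble: `compound_id`, `name`, `mw`, `logp`, `hbd`,
#'   `hba`, `rotb`, `tpsa`, `tcm_ids`, `features`, `latent_site`.
#' @export
generate_compound_library <- function(spec, catalog,
                                      templates = list(
                                        orthosteric = example_pharmacophore("orthosteric"),
                                        allosteric = example_pharmacophore("allosteric")
                                      )) {
  assert_that(nrow(catalog) >= 1, "catalog must be nonempty")
  hit_sites <- setdiff(names(spec$site_probs), "none")
  assert_that(all(hit_sites %in% names(templates)),
              "every hit site needs a template in `templates`")
  pd <- spec$property_distributions
  with_stream(spec$seed, "compound_library", {
    n <- spec$n_compounds
    sites <- sample(names(spec$site_probs), n, replace = TRUE,
                    prob = spec$site_probs)
    carry <- lapply(spec$planted, function(p) {
      vapply(catalog$flavors, function(v) p$flavor %in% v, logical(1))
    })
    base_frac <- vapply(carry, mean, double(1))
    tcm_ids <- vector("list", n)
    features <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample(1:3, 1)
      s <- sites[i]
      if (s %in% names(spec$planted) && any(carry[[s]]) && !all(carry[[s]])) {
        p_link <- min(1, base_frac[[s]] + spec$planted[[s]]$delta)
        pick <- function() {
          if (runif(1) < p_link) sample(which(carry[[s]]), 1)
          else sample(which(!carry[[s]]), 1)
        }
        idx <- unique(replicate(k, pick()))
      } else {
        idx <- unique(sample.int(nrow(catalog), k, replace = TRUE))
      }
      tcm_ids[[i]] <- catalog$tcm_id[idx]
      if (s == "none") {
        nf <- sample(3:6, 1)
        features[[i]] <- tibble(
          kind = sample(FEATURE_KINDS, nf, replace = TRUE),
          x = runif(nf, -5, 5), y = runif(nf, -5, 5), z = runif(nf, -5, 5)
        )
      } else {
        tf <- templates[[s]]$features
        jit <- matrix(runif(3 * nrow(tf), -1, 1), ncol = 3)
        norms <- sqrt(rowSums(jit^2))
        norms[norms == 0] <- 1
        jit <- jit / norms * runif(nrow(tf), 0, tf$tolerance / 2)
        features[[i]] <- tibble(
          kind = tf$kind,
          x = tf$x + jit[, 1], y = tf$y + jit[, 2], z = tf$z + jit[, 3]
        )
      }
    }
    tibble(
      compound_id = sprintf("CMP%05d", seq_len(n)),
      name = sprintf("compound-%05d", seq_len(n)),
      mw = rlnorm(n, pd$mw$meanlog, pd$mw$sdlog),
      logp = rnorm(n, pd$logp$mean, pd$logp$sd),
      hbd = rpois(n, pd$hbd$lambda),
      hba = rpois(n, pd$hba$lambda),
      rotb = rpois(n, pd$rotb$lambda),
      tpsa = rgamma(n, shape = pd$tpsa$shape, scale = pd$tpsa$scale),
      tcm_ids = tcm_ids,
      features = features,
      latent_site = sites
    )
  })
}

# smallest and largest sum of squared differences achievable when pairing
# positions `pos` with ranks `ranks` (rearrangement inequality)
.d2_bounds <- function(pos, ranks) {
  ps <- sort(pos)
  rs <- sort(ranks)
  c(min = sum((ps - rs)^2), max = sum((ps - rev(rs))^2))
}

# deterministic DFS for a permutation pi of 1..n with sum((i - pi_i)^2) == target
find_permutation_with_d2 <- function(n, target) {
  perm <- integer(n)
  used <- logical(n)
  search <- function(i, remaining) {
    if (i > n) return(remaining == 0)
    rest_pos <- seq.int(i + 1L, length.out = n - i)
    for (r in which(!used)) {
      left <- remaining - (i - r)^2
      if (left < 0) next
      if (n - i > 0) {
        rest_ranks <- setdiff(which(!used), r)
        b <- .d2_bounds(rest_pos, rest_ranks)
        if (left < b["min"] || left > b["max"]) next
      } else if (left != 0) next
      perm[i] <<- r
      used[r] <<- TRUE
      if (search(i + 1L, left)) return(TRUE)
      used[r] <<- FALSE
    }
    FALSE
  }
  if (!search(1L, target)) return(NULL)
  perm
}

#' Generate a binder table with an exact rank concordance
#'
#' Builds `n` binders whose Ki values are strictly increasing and whose
#' docking scores are constructed so that the descending score ranks form
#' a permutation with exactly `sum_d2` squared rank difference against the
#' ascending Ki ranks. [spearman_rho()] on the result therefore returns
#' `1 - 6 * sum_d2 / (n (n^2 - 1))` exactly, giving the statistics path an
#' analytic oracle.
#'
#' @param n number of binders.
#' @param sum_d2 target squared rank difference (must be achievable: even,
#'   between 0 and `n (n^2 - 1) / 3`).
#' @param seed integer seed for the Ki draw.
#' @return a binder tibble: `compound_id`, `ki_nM`, `total_score`.
#' @export
#' @examples
#' b <- generate_binder_table(7, 4, seed = 1)
#' spearman_rho(b$ki_nM, b$total_score)$rho  # 1 - 24/336
generate_binder_table <- function(n, sum_d2, seed = 0L) {
  assert_that(n >= 2, "`n` must be >= 2")
  perm <- find_permutation_with_d2(n, sum_d2)
  if (is.null(perm)) {
    abort(sprintf("sum_d2 = %d is not achievable for n = %d", sum_d2, n))
  }
  with_stream(seed, "binder_table", {
    ki <- sort(round(rlnorm(n, meanlog = log(5000), sdlog = 1.5))) + seq_len(n)
    tibble(
      compound_id = sprintf("SYN%03d", seq_len(n)),
      ki_nM = as.double(ki),
      total_score = 10 - 0.5 * perm
    )
  })
}

#' Generate a pose pair with an exact RMSD
#'
#' Returns a random reference pose and a displaced copy whose paired-atom
#' RMSD (no superposition) equals `target_rmsd` to within 1e-9 Angstrom,
#' by scaling random per-atom displacements.
#'
#' @param n_atoms number of atoms.
#' @param target_rmsd desired RMSD in Angstrom (>= 0).
#' @param seed integer seed.
#' @return a list of two `pose_coordinates`.
#' @export
generate_pose_pair <- function(n_atoms, target_rmsd, seed = 0L) {
  assert_that(n_atoms >= 1, "`n_atoms` must be >= 1")
  assert_that(target_rmsd >= 0, "`target_rmsd` must be >= 0")
  with_stream(seed, "pose_pair", {
    a <- matrix(rnorm(3 * n_atoms, sd = 3), ncol = 3)
    if (target_rmsd == 0) {
      b <- a
    } else {
      d <- matrix(rnorm(3 * n_atoms), ncol = 3)
      d <- d * (target_rmsd / sqrt(mean(rowSums(d^2))))
      b <- a + d
    }
    ids <- rep(c("C", "N", "O"), length.out = n_atoms)
    list(pose_coordinates(ids, a), pose_coordinates(ids, b))
  })
}
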