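## Reconstruction of active sites in 3D: cluster per-chain catalytic-residue
## hits into sites, validate the reconstructed geometry against the family
## reference and the sibling sites of the same structure, and remove
## redundant copies arising from assembly symmetry.

## All catalytic-residue hits in a structure: polymer residues matching a
## reference slot's (name, number) in any chain.
find_catalytic_hits <- function(struct, reference) {
  slots <- reference$residues
  defs <- unique(do.call(rbind, lapply(slots, function(r) {
    data.frame(name = r$name, number = r$number, stringsAsFactors = FALSE)
  })))
  a <- struct$atoms[!struct$atoms$het, , drop = FALSE]
  hits <- list()
  for (k in seq_len(nrow(defs))) {
    sel <- a$resid == defs$name[k] & a$resno == defs$number[k]
    if (!any(sel)) next
    for (ch in unique(a$chain[sel])) {
      atoms <- a[sel & a$chain == ch, , drop = FALSE]
      hits[[length(hits) + 1L]] <- list(
        name = defs$name[k], number = defs$number[k], chain = ch,
        atoms = atom_table(name = atoms$elety, element = atoms$element,
                           x = atoms$x, y = atoms$y, z = atoms$z,
                           occupancy = atoms$occupancy,
                           altloc = atoms$altloc),
        com = c(mean(atoms$x), mean(atoms$y), mean(atoms$z)))
    }
  }
  hits
}

#' Cluster catalytic residues of a structure into active sites
#'
#' Seeds each cluster with the first unassigned annotated residue in
#' (chain, residue number) lexicographic order, then grows it greedily:
#' among all unfilled reference slots, the candidate residue closest to the
#' current cluster's centre of mass (all heavy atoms, unit masses) is added,
#' ties broken by lower (chain, residue number). The equivalence criterion
#' for slot assignment is (residue name, residue number, equivalence group),
#' so symmetric interface sites contributing equivalent residue pairs from
#' two subunits are disambiguated. Every annotated residue ends up in at most
#' one site; unfillable slots are recorded as explicit gaps.
#'
#' @param struct a [structure3d()] object.
#' @param family a [family_annotation()]; its reference defines the slots.
#' @return list of [active_site()] objects (possibly empty).
#' @export
cluster_catalytic_residues <- function(struct, family) {
  reference <- family$reference
  slots <- reference$residues
  nslot <- length(slots)
  hits <- find_catalytic_hits(struct, reference)
  if (!length(hits)) return(list())
  hit_chain <- vapply(hits, `[[`, character(1), "chain")
  hit_name <- vapply(hits, `[[`, character(1), "name")
  hit_number <- vapply(hits, `[[`, integer(1), "number")
  unassigned <- rep(TRUE, length(hits))
  lex_order <- order(hit_chain, hit_number, hit_name)
  slot_name <- vapply(slots, `[[`, character(1), "name")
  slot_number <- vapply(slots, `[[`, integer(1), "number")
  slot_equiv <- vapply(slots, `[[`, integer(1), "equiv_group")

  sites <- list()
  while (any(unassigned)) {
    seed_hit <- lex_order[unassigned[lex_order]][1]
    seed_slots <- which(slot_name == hit_name[seed_hit] &
                          slot_number == hit_number[seed_hit])
    if (!length(seed_slots)) { # hit matches no slot; drop it
      unassigned[seed_hit] <- FALSE
      next
    }
    assignment <- rep(NA_integer_, nslot)
    seed_slot <- seed_slots[order(slot_equiv[seed_slots])][1]
    assignment[seed_slot] <- seed_hit
    unassigned[seed_hit] <- FALSE
    repeat {
      cluster_atoms <- do.call(rbind, lapply(assignment[!is.na(assignment)],
                                             function(h) {
        as.matrix(hits[[h]]$atoms[, c("x", "y", "z")])
      }))
      center <- com3(cluster_atoms)
      open_slots <- which(is.na(assignment))
      best <- NULL
      for (s in open_slots) {
        cand <- which(unassigned & hit_name == slot_name[s] &
                        hit_number == slot_number[s])
        ## exclude candidates already claimed by other open slots? no --
        ## each candidate may fill any matching slot; nearest wins
        for (h in cand) {
          d <- dist3(hits[[h]]$com, center)
          if (is.null(best) || d < best$d - 1e-12 ||
              (abs(d - best$d) <= 1e-12 &&
                 (hit_chain[h] < hit_chain[best$h] ||
                    (hit_chain[h] == hit_chain[best$h] &&
                       hit_number[h] < hit_number[best$h])))) {
            best <- list(s = s, h = h, d = d)
          }
        }
      }
      if (is.null(best)) break
      assignment[best$s] <- best$h
      unassigned[best$h] <- FALSE
    }
    residues <- vector("list", nslot)
    for (s in which(!is.na(assignment))) {
      h <- hits[[assignment[s]]]
      ref <- slots[[s]]
      residues[[s]] <- catalytic_residue(
        chain = h$chain, name = h$name, number = h$number,
        function_location = ref$function_location, role = ref$role,
        role_category = ref$role_category, equiv_group = ref$equiv_group,
        atoms = h$atoms)
    }
    sites[[length(sites) + 1L]] <- active_site(
      site_id = sprintf("%s_site%d", struct$structure_id, length(sites) + 1L),
      structure_id = struct$structure_id, residues = residues,
      resolution = reference$resolution, experiment = "xray",
      sequence_accession = NA_character_)
  }
  sites
}

#' Check the structural sanity of a reconstructed active site
#'
#' Rule 1 (vs reference): every inter-residue centre-of-mass distance above
#' 8 Angstrom must be at most 3 times the corresponding distance in the
#' reference site. Rule 2 (vs siblings): against every other site built from
#' the same structure, each distance must be at most 1.3 times the distance
#' of the equivalent residue pair. Pairs whose reference (or sibling) slot is
#' null are skipped and logged in the `skipped` attribute.
#'
#' @param site site under test, positionally aligned to `reference`.
#' @param reference the family reference site (ground truth geometry).
#' @param siblings other sites reconstructed from the same structure.
#' @param far_cutoff distance gate for rule 1 (Angstrom).
#' @param ref_factor,sibling_factor multipliers for rules 1 and 2.
#' @return list of class `sanity_verdict`: `passed` flag and `failed_pairs`
#'   data frame (slot_i, slot_j, observed, limit, rule).
#' @export
check_site_sanity <- function(site, reference, siblings = list(),
                              far_cutoff = 8, ref_factor = 3,
                              sibling_factor = 1.3) {
  idx <- filled_slots(site)
  coms <- lapply(site$residues, function(r) if (!is.null(r)) residue_com(r))
  ref_coms <- lapply(reference$residues,
                     function(r) if (!is.null(r)) residue_com(r))
  failed <- list()
  skipped <- list()
  add_fail <- function(i, j, obs, limit, rule) {
    failed[[length(failed) + 1L]] <<- data.frame(
      slot_i = i, slot_j = j, observed = obs, limit = limit, rule = rule,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(idx) >= 2) utils::combn(idx, 2) else
    matrix(integer(0), 2, 0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d_obs <- dist3(coms[[i]], coms[[j]])
    if (d_obs > far_cutoff) {
      if (is.null(ref_coms[[i]]) || is.null(ref_coms[[j]])) {
        skipped[[length(skipped) + 1L]] <- c(i, j)
      } else {
        d_ref <- dist3(ref_coms[[i]], ref_coms[[j]])
        if (d_obs > ref_factor * d_ref) {
          add_fail(i, j, d_obs, ref_factor * d_ref, "vs_reference_3x")
        }
      }
    }
    for (sib in siblings) {
      si <- sib$residues[[i]]; sj <- sib$residues[[j]]
      if (is.null(si) || is.null(sj)) {
        skipped[[length(skipped) + 1L]] <- c(i, j)
        next
      }
      d_sib <- dist3(residue_com(si), residue_com(sj))
      if (d_obs > sibling_factor * d_sib) {
        add_fail(i, j, d_obs, sibling_factor * d_sib, "vs_sibling_1p3x")
      }
    }
  }
  failed_pairs <- if (length(failed)) do.call(rbind, failed) else
    data.frame(slot_i = integer(0), slot_j = integer(0),
               observed = numeric(0), limit = numeric(0),
               rule = character(0), stringsAsFactors = FALSE)
  structure(list(passed = nrow(failed_pairs) == 0,
                 failed_pairs = failed_pairs),
            skipped = skipped, class = "sanity_verdict")
}

#' @export
print.sanity_verdict <- function(x, ...) {
  if (x$passed) cat("<sanity_verdict> passed\n")
  else {
    cat(sprintf("<sanity_verdict> FAILED (%d pair(s)):\n",
                nrow(x$failed_pairs)))
    print(x$failed_pairs)
  }
  invisible(x)
}

#' Remove redundant active-site copies within one structure
#'
#' Greedy retention in input order: a site is dropped when its weighted RMSD
#' to any already retained site is below the threshold. This removes
#' duplicate sites created by copying asymmetric-unit chains into the
#' biological assembly.
#'
#' @param sites sites from one structure, pairwise superposable.
#' @param threshold RMSD threshold in Angstrom (default 0.5, an estimate of
#'   coordinate uncertainty at typical resolutions).
#' @param params superposition parameters.
#' @return the retained subset, input order preserved.
#' @export
deduplicate_sites <- function(sites, threshold = 0.5,
                              params = superposition_params()) {
  kept <- list()
  for (s in sites) {
    dup <- FALSE
    for (k in kept) {
      w <- tryCatch(gaussian_weighted_superpose(s, k, params)$wrmsd,
                    error = function(e) NA_real_)
      if (!is.na(w) && w < threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- s
  }
  kept
}

#' Reconstruct, validate and deduplicate the active sites of one structure
#'
#' Orchestrates [cluster_catalytic_residues()], [check_site_sanity()] (sites
#' failing either sanity rule are discarded) and [deduplicate_sites()].
#'
#' @inheritParams cluster_catalytic_residues
#' @inheritParams deduplicate_sites
#' @return list of validated sites; attribute `"rejected"` holds the site ids
#'   that failed sanity together with their verdicts.
#' @export
build_active_sites <- function(struct, family, threshold = 0.5,
                               params = superposition_params()) {
  sites <- cluster_catalytic_residues(struct, family)
  verdicts <- lapply(seq_along(sites), function(i) {
    check_site_sanity(sites[[i]], family$reference, sites[-i])
  })
  ok <- vapply(verdicts, `[[`, logical(1), "passed")
  rejected <- lapply(which(!ok), function(i) {
    list(site_id = sites[[i]]$site_id, verdict = verdicts[[i]])
  })
  structure(deduplicate_sites(sites[ok], threshold, params),
            rejected = rejected)
}
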