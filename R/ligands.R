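## Ligand identification and annotation: radius searches around the
## catalytic residues (with pseudo-centres bridging gaps between distant
## residues), classification of each component as substrate-like / cofactor /
## artefact / uncertain, and a centrality metric locating the ligand relative
## to the catalytic residues.

ligand_record <- function(comp_id, proximity, chain = NA_character_,
                          resno = NA_integer_, atoms = NULL,
                          ligand_class = "uncertain",
                          best_match = NA_character_,
                          similarity = NA_real_, centrality = NA_real_) {
  structure(list(comp_id = comp_id, proximity = proximity, chain = chain,
                 resno = resno, atoms = atoms, ligand_class = ligand_class,
                 best_match = best_match, similarity = similarity,
                 centrality = centrality),
            class = "ligand_record")
}

#' @export
print.ligand_record <- function(x, ...) {
  cat(sprintf("<ligand %s> %s, class %s%s%s\n", x$comp_id, x$proximity,
              x$ligand_class,
              if (!is.na(x$similarity))
                sprintf(", similarity %.2f to %s", x$similarity, x$best_match)
              else "",
              if (!is.na(x$centrality))
                sprintf(", centrality %.2f", x$centrality) else ""))
  invisible(x)
}

## search centres: every catalytic atom, plus a pseudo-centre at the average
## centre of mass of each residue pair whose COM separation exceeds the gap
## cutoff (fills the volume between distant residues whose search spheres
## cannot overlap)
site_search_centers <- function(site, pseudo_gap = 6) {
  idx <- filled_slots(site)
  centers <- do.call(rbind, lapply(site$residues[idx], residue_xyz))
  coms <- lapply(site$residues[idx], residue_com)
  if (length(coms) >= 2) {
    pairs <- utils::combn(length(coms), 2)
    for (k in seq_len(ncol(pairs))) {
      ci <- coms[[pairs[1, k]]]; cj <- coms[[pairs[2, k]]]
      if (dist3(ci, cj) > pseudo_gap) {
        centers <- rbind(centers, (ci + cj) / 2)
      }
    }
  }
  centers
}

## minimum distance from any of `points` (m x 3) to any of `centers` (n x 3)
min_cross_distance <- function(points, centers) {
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") -
    2 * tcrossprod(points, centers)
  sqrt(max(0, min(d2)))
}

## hetero component instances of a structure: one per (chain, resno, resid)
hetero_instances <- function(struct) {
  a <- struct$atoms[struct$atoms$het, , drop = FALSE]
  if (!nrow(a)) return(list())
  key <- paste(a$chain, a$resno, a$resid, sep = "|")
  lapply(split(seq_len(nrow(a)), key), function(rows) {
    sub <- a[rows, , drop = FALSE]
    list(comp_id = sub$resid[1], chain = sub$chain[1], resno = sub$resno[1],
         atoms = atom_table(name = sub$elety, element = sub$element,
                            x = sub$x, y = sub$y, z = sub$z,
                            occupancy = sub$occupancy, altloc = sub$altloc))
  })
}

#' Find components adjacent to an active site
#'
#' Spherical search of `radius` around every catalytic atom, plus
#' pseudo-centres between residues more than `pseudo_gap` apart (see
#' [site_search_centers()] logic). Captures hetero components and polymer
#' residues from chains not contributing to the site; captured polymer
#' residues are merged into a single `"POLYMER"` record per chain segment,
#' not reported individually.
#'
#' @param site an [active_site()] built from `struct`.
#' @param struct the source [structure3d()].
#' @param radius search radius in Angstrom (default 3).
#' @param pseudo_gap maximum distance between search centres before a
#'   pseudo-centre is interpolated (Angstrom, default 6).
#' @return list of `ligand_record`s with `proximity = "adjacent"`,
#'   unclassified (see [classify_ligand()]).
#' @export
find_adjacent_ligands <- function(site, struct, radius = 3, pseudo_gap = 6) {
  centers <- site_search_centers(site, pseudo_gap)
  records <- list()
  for (inst in hetero_instances(struct)) {
    pts <- as.matrix(inst$atoms[, c("x", "y", "z")])
    if (min_cross_distance(pts, centers) <= radius) {
      records[[length(records) + 1L]] <- ligand_record(
        comp_id = inst$comp_id, proximity = "adjacent", chain = inst$chain,
        resno = inst$resno, atoms = inst$atoms)
    }
  }
  ## polymer residues from foreign chains, merged per chain segment
  site_chains <- unique(vapply(site$residues[filled_slots(site)],
                               `[[`, character(1), "chain"))
  a <- struct$atoms[!struct$atoms$het &
                      !(struct$atoms$chain %in% site_chains), , drop = FALSE]
  if (nrow(a)) {
    for (ch in unique(a$chain)) {
      sub <- a[a$chain == ch, , drop = FALSE]
      key <- paste(sub$resno, sub$resid)
      captured <- vapply(split(seq_len(nrow(sub)), key), function(rows) {
        pts <- as.matrix(sub[rows, c("x", "y", "z")])
        min_cross_distance(pts, centers) <= radius
      }, logical(1))
      if (any(captured)) {
        rows <- unlist(split(seq_len(nrow(sub)), key)[captured])
        seg <- sub[rows, , drop = FALSE]
        records[[length(records) + 1L]] <- ligand_record(
          comp_id = "POLYMER", proximity = "adjacent", chain = ch,
          resno = min(seg$resno),
          atoms = atom_table(name = seg$elety, element = seg$element,
                             x = seg$x, y = seg$y, z = seg$z,
                             occupancy = seg$occupancy, altloc = seg$altloc))
      }
    }
  }
  records
}

#' Find cofactor-like and substrate-like components peripheral to a site
#'
#' Searches a sphere of `radius` centred at the active-site centroid,
#' excluding components already captured as adjacent, classifies the hits and
#' keeps only substrate-like and cofactor components, flagged `"distal"`.
#'
#' @inheritParams find_adjacent_ligands
#' @param radius search radius in Angstrom (default 30).
#' @param adjacent result of [find_adjacent_ligands()] for exclusion.
#' @param cognates list of cognate reaction components ([small_molecule()]).
#' @param molecules component chemistry lookup, named by comp id.
#' @param cofactor_table,artefact_table component code tables.
#' @return list of classified distal `ligand_record`s.
#' @export
find_distal_components <- function(site, struct, radius = 30,
                                   adjacent = list(),
                                   cognates = list(),
                                   molecules = default_molecules(),
                                   cofactor_table = default_cofactor_table(),
                                   artefact_table = default_artefact_table()) {
  centroid <- matrix(com3(site_xyz(site)), 1, 3)
  adj_keys <- vapply(adjacent, function(r) {
    paste(r$chain, r$resno, r$comp_id, sep = "|")
  }, character(1))
  records <- list()
  for (inst in hetero_instances(struct)) {
    key <- paste(inst$chain, inst$resno, inst$comp_id, sep = "|")
    if (key %in% adj_keys) next
    pts <- as.matrix(inst$atoms[, c("x", "y", "z")])
    if (min_cross_distance(pts, centroid) > radius) next
    rec <- classify_ligand(
      ligand_record(comp_id = inst$comp_id, proximity = "distal",
                    chain = inst$chain, resno = inst$resno,
                    atoms = inst$atoms),
      cognates = cognates, molecules = molecules,
      cofactor_table = cofactor_table, artefact_table = artefact_table)
    if (rec$ligand_class %in% c("substrate_like", "cofactor")) {
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Classify a ligand from its best cognate similarity and the code tables
#'
#' Decision pipeline, applied in order: substrate-like if the best similarity
#' to a cognate reaction component is at least `substrate_cut` (0.6);
#' otherwise cofactor if the component code is in the cofactor table (this is
#' where ionic/non-ionic cofactors and single-atom components land, their
#' similarity being undefined); otherwise artefact if the code is in the
#' crystallisation-artefact table and the best similarity does not exceed
#' `artefact_cut` (0.3); otherwise uncertain.
#'
#' @param comp_id component code.
#' @param similarity best cognate similarity, or `NA` if undefined.
#' @param cofactor_table,artefact_table component code tables.
#' @param substrate_cut,artefact_cut decision thresholds.
#' @return class label string.
#' @export
classify_from_similarity <- function(comp_id, similarity,
                                     cofactor_table, artefact_table,
                                     substrate_cut = 0.6,
                                     artefact_cut = 0.3) {
  if (!is.na(similarity) && similarity >= substrate_cut) {
    return("substrate_like")
  }
  if (comp_id %in% cofactor_table) return("cofactor")
  if (comp_id %in% artefact_table &&
      (is.na(similarity) || similarity <= artefact_cut)) {
    return("artefact")
  }
  "uncertain"
}

#' Classify a ligand record against cognate reaction components
#'
#' Computes the chemical similarity ([parity_similarity()]) of the ligand to
#' every cognate reactant/product, annotates the best match (ties broken by
#' lexicographically smallest comp id), and applies the decision pipeline of
#' [classify_from_similarity()]. Similarity is undefined (null) for polymers,
#' single-atom components, and components without chemistry in `molecules`.
#'
#' @param ligand a `ligand_record`.
#' @param cognates list of [small_molecule()] cognate components.
#' @param molecules named list of component chemistry definitions.
#' @param cofactor_table,artefact_table component code tables.
#' @param substrate_cut,artefact_cut decision thresholds.
#' @return the ligand record with `ligand_class`, `best_match` and
#'   `similarity` filled in.
#' @export
classify_ligand <- function(ligand, cognates = list(),
                            molecules = default_molecules(),
                            cofactor_table = default_cofactor_table(),
                            artefact_table = default_artefact_table(),
                            substrate_cut = 0.6, artefact_cut = 0.3) {
  sim <- NA_real_
  best <- NA_character_
  mol <- molecules[[ligand$comp_id]]
  if (ligand$comp_id != "POLYMER" && !is.null(mol) &&
      length(mol$elements) >= 2 && length(cognates)) {
    ids <- vapply(cognates, `[[`, character(1), "comp_id")
    sims <- vapply(cognates, function(cg) {
      s <- parity_similarity(mol, cg)
      if (is.na(s)) -Inf else s
    }, numeric(1))
    if (any(is.finite(sims))) {
      m <- max(sims)
      cand <- sort(unname(ids[sims == m]))
      sim <- unname(m)
      best <- cand[1]
    }
  }
  ligand$similarity <- sim
  ligand$best_match <- best
  ligand$ligand_class <- classify_from_similarity(
    ligand$comp_id, sim, cofactor_table, artefact_table,
    substrate_cut, artefact_cut)
  ligand
}

#' Centrality of a ligand relative to the catalytic residues
#'
#' Mean centre-of-mass distance of the ligand to the catalytic residues,
#' normalised over the mean inter-residue centre-of-mass distance. Small
#' values mean the ligand sits amid the catalytic residues.
#'
#' @param ligand a `ligand_record` with atoms.
#' @param site the active site.
#' @return non-negative real, or `NA_real_` for sites with fewer than two
#'   filled residue slots (undefined).
#' @export
ligand_centrality <- function(ligand, site) {
  idx <- filled_slots(site)
  if (length(idx) < 2) return(NA_real_)
  lig_com <- com3(as.matrix(ligand$atoms[, c("x", "y", "z")]))
  coms <- t(vapply(site$residues[idx], residue_com, numeric(3)))
  num <- mean(sqrt(rowSums((coms - matrix(lig_com, nrow(coms), 3,
                                          byrow = TRUE))^2)))
  den <- mean(stats::dist(coms))
  num / den
}

#' Annotate all ligands of an active site
#'
#' Orchestrates the adjacent and distal searches, classification and
#' centrality scoring, returning one table row per captured component.
#'
#' @inheritParams find_distal_components
#' @param adjacent_radius,distal_radius search radii (Angstrom).
#' @param pseudo_gap pseudo-centre gap cutoff (Angstrom).
#' @return data.frame with columns site_id, comp_id, proximity, ligand_class,
#'   best_match, similarity, centrality, chain, resno.
#' @export
annotate_ligands <- function(site, struct, cognates = list(),
                             molecules = default_molecules(),
                             cofactor_table = default_cofactor_table(),
                             artefact_table = default_artefact_table(),
                             adjacent_radius = 3, distal_radius = 30,
                             pseudo_gap = 6) {
  adj <- find_adjacent_ligands(site, struct, adjacent_radius, pseudo_gap)
  adj <- lapply(adj, function(r) {
    r <- classify_ligand(r, cognates, molecules, cofactor_table,
                         artefact_table)
    r$centrality <- ligand_centrality(r, site)
    r
  })
  dist_ <- find_distal_components(site, struct, distal_radius, adjacent = adj,
                                  cognates = cognates, molecules = molecules,
                                  cofactor_table = cofactor_table,
                                  artefact_table = artefact_table)
  dist_ <- lapply(dist_, function(r) {
    r$centrality <- ligand_centrality(r, site)
    r
  })
  all_ <- c(adj, dist_)
  if (!length(all_)) {
    return(data.frame(site_id = character(0), comp_id = character(0),
                      proximity = character(0), ligand_class = character(0),
                      best_match = character(0), similarity = numeric(0),
                      centrality = numeric(0), chain = character(0),
                      resno = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(site_id = site$site_id,
             comp_id = vapply(all_, `[[`, character(1), "comp_id"),
             proximity = vapply(all_, `[[`, character(1), "proximity"),
             ligand_class = vapply(all_, `[[`, character(1), "ligand_class"),
             best_match = vapply(all_, `[[`, character(1), "best_match"),
             similarity = vapply(all_, `[[`, numeric(1), "similarity"),
             centrality = vapply(all_, `[[`, numeric(1), "centrality"),
             chain = vapply(all_, `[[`, character(1), "chain"),
             resno = vapply(all_, `[[`, integer(1), "resno"),
             stringsAsFactors = FALSE)
}

#' Is a site ligand-bound?
#'
#' A site counts as bound when at least one adjacent, non-artefact,
#' native-like component is present: class substrate-like or cofactor.
#'
#' @param ligand_report data.frame from [annotate_ligands()] (one site).
#' @return logical.
#' @export
site_is_bound <- function(ligand_report) {
  any(ligand_report$proximity == "adjacent" &
        ligand_report$ligand_class %in% c("substrate_like", "cofactor"))
}
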