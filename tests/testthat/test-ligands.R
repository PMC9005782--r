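## structure with two single-atom catalytic residues `gap` Angstrom apart on
## the x axis plus hetero/polymer components at controlled positions
two_residue_struct <- function(gap = 10, extra = NULL) {
  atoms <- data.frame(
    type = "ATOM", chain = "A", resno = c(1L, 2L), resid = "GLY",
    elety = "CA", element = "C", x = c(0, gap), y = 0, z = 0,
    occupancy = 1, altloc = "", stringsAsFactors = FALSE)
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  structure3d(atoms, "lig_1")
}

two_residue_site <- function(gap = 10) {
  point_site("site", rbind(c(0, 0, 0), c(gap, 0, 0)), numbers = c(1L, 2L))
}

het_atom <- function(resid, x, y = 0, z = 0, chain = "X", resno = 900L,
                     elety = "O1", element = "O") {
  data.frame(type = "HETATM", chain = chain, resno = resno, resid = resid,
             elety = elety, element = element, x = x, y = y, z = z,
             occupancy = 1, altloc = "", stringsAsFactors = FALSE)
}

test_that("adjacent search captures by distance and pseudo-centres", {
  ## water at 2.5 A from a catalytic atom: captured
  s <- two_residue_struct(extra = het_atom("HOH", x = 0, y = 2.5))
  rec <- find_adjacent_ligands(two_residue_site(), s)
  expect_equal(vapply(rec, `[[`, character(1), "comp_id"), "HOH")
  ## at 3.5 A off-axis (away from any pseudo-centre): not captured
  s2 <- two_residue_struct(extra = het_atom("HOH", x = 0, y = 3.5))
  expect_length(find_adjacent_ligands(two_residue_site(), s2), 0)
  ## ligand at the midpoint of two residues 10 A apart: beyond 3 A of every
  ## atom, captured only through the interpolated pseudo-centre
  s3 <- two_residue_struct(extra = het_atom("LAC", x = 5))
  expect_equal(find_adjacent_ligands(two_residue_site(), s3)[[1]]$comp_id,
               "LAC")
  ## with residues 5 A apart (below the 6 A gap cutoff) no pseudo-centre is
  ## added, so a midpoint ligand 3.5 A off-axis stays uncaptured
  s4 <- two_residue_struct(gap = 5,
                           extra = het_atom("LAC", x = 2.5, y = 3.5))
  expect_length(find_adjacent_ligands(two_residue_site(gap = 5), s4), 0)
})

test_that("foreign-chain polymer stretches merge into one POLYMER record", {
  pep <- do.call(rbind, lapply(1:4, function(i) {
    het <- data.frame(type = "ATOM", chain = "P", resno = i, resid = "ALA",
                      elety = "CA", element = "C", x = 1.5 * i, y = 2,
                      z = 0, occupancy = 1, altloc = "",
                      stringsAsFactors = FALSE)
  }))
  s <- two_residue_struct(extra = pep)
  rec <- find_adjacent_ligands(two_residue_site(), s)
  expect_length(rec, 1)
  expect_equal(rec[[1]]$comp_id, "POLYMER")
  expect_equal(nrow(rec[[1]]$atoms), 4)
  ## residues of the site's own chains are never ligands
  expect_length(find_adjacent_ligands(two_residue_site(),
                                      two_residue_struct()), 0)
})

test_that("distal search keeps classified cofactors within 30 A only", {
  mk <- function(x) two_residue_struct(extra = het_atom("ZN", x = x,
                                                        elety = "ZN",
                                                        element = "ZN"))
  site <- two_residue_site()
  ## centroid is at x = 5: a ZN 12 A away is distal
  rec <- find_distal_components(site, mk(17))
  expect_length(rec, 1)
  expect_equal(rec[[1]]$proximity, "distal")
  expect_equal(rec[[1]]$ligand_class, "cofactor")
  ## beyond 30 A: absent
  expect_length(find_distal_components(site, mk(40)), 0)
  ## already adjacent: not duplicated as distal
  s_adj <- mk(1)
  adj <- find_adjacent_ligands(site, s_adj)
  expect_length(adj, 1)
  expect_length(find_distal_components(site, s_adj, adjacent = adj), 0)
  ## artefact-class hetero components are not reported distally
  s_gol <- two_residue_struct(extra = het_atom("GOL", x = 15))
  expect_length(find_distal_components(site, s_gol), 0)
})

test_that("similarity score matches closed forms and the exhaustive oracle", {
  mols <- default_molecules()
  expect_equal(parity_similarity(mols$GOL, mols$GOL), 1)
  expect_equal(parity_similarity(mols$ETH, mols$EOH), 2 / 3)
  ## disjoint element sets
  expect_equal(parity_similarity(mols$ETH, mols$SO4), 0)
  ## single-atom components are undefined
  expect_true(is.na(parity_similarity(mols$ZN, mols$GOL)))
  ## symmetry and the unmatched-atom property
  expect_equal(parity_similarity(mols$EOH, mols$GOL),
               parity_similarity(mols$GOL, mols$EOH))
  eoh_plus <- small_molecule("XXX", c("C", "C", "O", "N"),
                             rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
  expect_lt(parity_similarity(eoh_plus, mols$ETH),
            parity_similarity(mols$EOH, mols$ETH))
  ## exhaustive oracle on a few molecule pairs (full sweep in acceptance)
  for (pair in list(c("EOH", "GOL"), c("PYR", "LAC"), c("ACT", "PYR"))) {
    a <- mols[[pair[1]]]; b <- mols[[pair[2]]]
    m <- brute_force_mcs(a, b)
    expect_equal(parity_similarity(a, b),
                 m / (length(a$elements) + length(b$elements) - m))
  }
})

test_that("classification applies the 60%/30% decision pipeline in order", {
  cof <- default_cofactor_table()
  art <- default_artefact_table()
  cls <- function(comp, sim) classify_from_similarity(comp, sim, cof, art)
  expect_equal(cls("ABC", 0.65), "substrate_like")
  expect_equal(cls("ABC", 0.60), "substrate_like") # boundary inclusive
  expect_equal(cls("GOL", 0.10), "artefact")
  expect_equal(cls("GOL", 0.30), "artefact")       # escape needs > 0.3
  expect_equal(cls("GOL", 0.31), "uncertain")
  expect_equal(cls("ZN", NA_real_), "cofactor")    # single atom, table hit
  expect_equal(cls("ZN", 0.95), "substrate_like")  # similarity first
  expect_equal(cls("ABC", NA_real_), "uncertain")
  expect_equal(cls("ABC", 0.45), "uncertain")
})

test_that("classify_ligand scores against cognates deterministically", {
  mols <- default_molecules()
  lig <- sitevar:::ligand_record("LAC", "adjacent",
                                 atoms = atom_table("C1", "C", 0, 0, 0))
  cognates <- mols[c("PYR", "GOL")]
  out <- classify_ligand(lig, cognates, molecules = mols)
  expect_equal(out$ligand_class, "substrate_like")
  expect_equal(out$best_match, "PYR")
  expect_equal(out$similarity, 1)
  ## permuting the cognate list changes nothing
  out2 <- classify_ligand(lig, rev(cognates), molecules = mols)
  expect_equal(out2$ligand_class, out$ligand_class)
  expect_equal(out2$best_match, out$best_match)
  ## equal-score ties resolve to the lexicographically smallest comp id
  twin <- mols$PYR
  twin$comp_id <- "AAA"
  out3 <- classify_ligand(lig, c(mols["PYR"], list(AAA = twin)),
                          molecules = mols)
  expect_equal(out3$best_match, "AAA")
  ## polymer records never get a similarity
  pol <- sitevar:::ligand_record("POLYMER", "adjacent",
                                 atoms = atom_table("CA", "C", 0, 0, 0))
  expect_true(is.na(classify_ligand(pol, cognates,
                                    molecules = mols)$similarity))
})

test_that("ligand centrality matches closed-form geometry", {
  s <- 6
  centers <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  site <- point_site("tri", centers)
  centroid <- colMeans(centers)
  at_centroid <- sitevar:::ligand_record(
    "LIG", "adjacent", atoms = atom_table("C1", "C", centroid[1],
                                          centroid[2], centroid[3]))
  expect_equal(ligand_centrality(at_centroid, site), 1 / sqrt(3),
               tolerance = 1e-9)
  at_vertex <- sitevar:::ligand_record(
    "LIG", "adjacent", atoms = atom_table("C1", "C", 0, 0, 0))
  expect_equal(ligand_centrality(at_vertex, site), 2 / 3, tolerance = 1e-9)
  lone <- point_site("one", matrix(c(0, 0, 0), 1))
  expect_true(is.na(ligand_centrality(at_vertex, lone)))
})

test_that("annotate_ligands reports bound state from native-like components", {
  asm <- generate_assembly(
    "homodimer",
    ligands = list(list(comp_id = "LAC", offset = c(0, 0, 2)),
                   list(comp_id = "SO4", offset = c(0, 0, -3))),
    seed = 11)
  sites <- build_active_sites(asm$struct, asm$family)
  mols <- default_molecules()
  rep1 <- annotate_ligands(sites[[1]], asm$struct, cognates = mols["PYR"])
  expect_true(site_is_bound(rep1))
  lac <- rep1[rep1$comp_id == "LAC", ]
  expect_equal(lac$ligand_class, "substrate_like")
  ## sulfate shares only oxygens with the cognate: similarity 1/10, artefact
  expect_equal(rep1$ligand_class[rep1$comp_id == "SO4"], "artefact")
  expect_equal(rep1$similarity[rep1$comp_id == "SO4"], 0.1)
  ## apo version of the same assembly
  apo <- generate_assembly("homodimer", seed = 11)
  sites0 <- build_active_sites(apo$struct, apo$family)
  rep0 <- annotate_ligands(sites0[[1]], apo$struct, cognates = mols["PYR"])
  expect_false(site_is_bound(rep0))
})
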