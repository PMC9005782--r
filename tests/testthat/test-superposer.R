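test_that("functional triads follow the residue's function location", {
  arg <- catalytic_residue("A", "ARG", 1, atoms = residue_template("ARG"))
  tri <- functional_triad(arg)
  expect_equal(tri$atom_names, c("CZ", "NH1", "NH2"))
  expect_equal(tri$symmetry_classes, list(c(2L, 3L)))
  expect_equal(tri$source, "side_chain")

  gly <- catalytic_residue("A", "GLY", 2, function_location = "main_chain",
                           atoms = residue_template("GLY"))
  expect_equal(functional_triad(gly)$atom_names, c("N", "CA", "C"))

  ## main-chain function overrides the side-chain table
  ser_mc <- catalytic_residue("A", "SER", 3, function_location = "main_chain",
                              atoms = residue_template("SER"))
  expect_equal(functional_triad(ser_mc)$atom_names, c("N", "CA", "C"))

  his <- catalytic_residue("A", "HIS", 4, atoms = residue_template("HIS"))
  expect_equal(functional_triad(his)$symmetry_classes, list(1:3))

  ## a missing triad atom demotes the slot to a gap, with a warning
  broken <- residue_template("ARG")
  broken <- broken[broken$name != "NH2", ]
  arg2 <- catalytic_residue("A", "ARG", 5, atoms = broken)
  expect_warning(tri2 <- functional_triad(arg2), "NH2")
  expect_null(tri2)
})

test_that("residue pairing distinguishes the three mutation types and gaps", {
  asp <- catalytic_residue("A", "ASP", 1, atoms = residue_template("ASP"))
  glu <- catalytic_residue("A", "GLU", 1, atoms = residue_template("GLU"))
  lys <- catalytic_residue("A", "LYS", 2, atoms = residue_template("LYS"))
  arg <- catalytic_residue("A", "ARG", 2, atoms = residue_template("ARG"))
  ser <- catalytic_residue("A", "SER", 3, atoms = residue_template("SER"))
  a <- active_site("a", "a_1", list(asp, lys, ser))
  b <- active_site("b", "b_1", list(glu, arg, NULL))
  pairs <- pair_residues(a, b)
  expect_equal(pairs[[1]]$kind, "conservative_mismatch")
  ## carboxylate triads pair positionally: CG<->CD, OD1<->OE1, OD2<->OE2
  expect_equal(pairs[[1]]$atoms_a, c("CG", "OD1", "OD2"))
  expect_equal(pairs[[1]]$atoms_b, c("CD", "OE1", "OE2"))
  expect_equal(pairs[[1]]$symmetry_classes, list(c(2L, 3L)))
  expect_equal(pairs[[2]]$kind, "nonequivalent_mismatch")
  expect_equal(pairs[[2]]$symmetry_classes, list(1:3))
  expect_equal(pairs[[3]]$kind, "gap")
})

test_that("symmetric side chains are resolved by the assignment step", {
  site <- ring_site("a")
  ## Asp terminal oxygens swapped in the partner file: resolved back, RMSD 0
  swapped <- swap_atom_coords(site, 1, "OD1", "OD2")
  swapped$site_id <- "b"
  res <- gaussian_weighted_superpose(site, swapped)
  expect_lt(res$wrmsd, 1e-6)
  ## His ring relabelled (ring flip): ND1/CE1/NE2 coordinates permuted
  flipped <- swap_atom_coords(site, 2, "ND1", "NE2")
  flipped$site_id <- "c"
  res2 <- gaussian_weighted_superpose(site, flipped)
  expect_lt(res2$wrmsd, 1e-6)
  ## name-order mapping (no symmetry classes) would leave a large residual:
  ## check via the resolved correspondence actually swapping the atoms
  corr <- res2$correspondence
  his_rows <- corr[corr$slot == 2, ]
  expect_true(any(his_rows$atom_a != his_rows$atom_b))
})

test_that("nonequivalent-mismatch assignment equals the brute-force minimum", {
  withr::with_seed(61, {
    for (k in 1:10) {
      site <- ring_site("a", types = c("ASP", "LYS", "SER", "THR"))
      other <- ring_site("b", types = c("ASP", "ARG", "SER", "THR"))
      other <- jitter_site(other, 0.2, seed = k, id = "b")
      pairs <- pair_residues(site, other)
      asm <- sitevar:::assemble_pairing(pairs)
      mapping <- sitevar:::resolve_mapping(asm$A, asm$B, asm$classes)
      ## brute force over the permutations of each exchange class, using the
      ## same crude-fit geometry the implementation uses
      cf <- sitevar:::crude_fit(asm$A, asm$B, asm$classes)
      At <- sitevar:::apply_transform(asm$A, cf$fit$rotation,
                                      cf$fit$translation)
      for (cl in asm$classes) {
        cost <- as.matrix(dist(rbind(At[cl, ], asm$B[cl, ])))
        cost <- cost[seq_along(cl), length(cl) + seq_along(cl)]
        got <- sum(cost[cbind(seq_along(cl), match(mapping[cl], cl))])
        expect_equal(got, brute_force_assignment(cost)$cost,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("identical sites superpose exactly in one iteration", {
  site <- ring_site("a")
  res <- gaussian_weighted_superpose(site, site)
  expect_equal(res$wrmsd, 0, tolerance = 1e-12)
  expect_true(all(res$per_residue_rmsd < 1e-12))
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
})

test_that("wRMSD is symmetric and invariant to rigid motion of either site", {
  a <- ring_site("a")
  b <- jitter_site(ring_site("b", seed = 99), 0.4, seed = 7, id = "b")
  ab <- gaussian_weighted_superpose(a, b)$wrmsd
  ba <- gaussian_weighted_superpose(b, a)$wrmsd
  expect_equal(ab, ba, tolerance = 1e-6)
  moved <- withr::with_seed(3, transform_site(b, sitevar:::random_rotation(),
                                              c(12, -5, 3)))
  expect_equal(gaussian_weighted_superpose(a, moved)$wrmsd, ab,
               tolerance = 1e-6)
})

test_that("the weighted fit locks onto the rigid core", {
  a <- ring_site("a")
  b <- displace_residue(a, 6, c(5, 0, 0))
  b$site_id <- "b"
  res <- gaussian_weighted_superpose(a, b)
  rigid <- res$per_residue_rmsd[as.character(1:5)]
  expect_true(all(rigid < 0.05))
  expect_gt(res$per_residue_rmsd["6"], 4.5)
  expect_lt(res$per_residue_rmsd["6"], 5.5)
  expect_equal(res$max_residue_rmsd, unname(res$per_residue_rmsd["6"]))
  ## the classical uniform fit smears the displacement over the core
  uniform <- gaussian_weighted_superpose(
    a, b, superposition_params(c_param = Inf))
  expect_gt(min(uniform$per_residue_rmsd[as.character(1:5)]), 0.3)
})

test_that("gap slots are excluded and too-small sites are an error", {
  a <- ring_site("a", types = c("ASP", "HIS", "SER"))
  residues <- a$residues
  residues[3] <- list(NULL)
  b <- active_site("b", "b_1", residues)
  res <- gaussian_weighted_superpose(a, b)
  expect_equal(sort(names(res$per_residue_rmsd)), c("1", "2"))
  expect_error(
    gaussian_weighted_superpose(
      active_site("e", "e_1", list(a$residues[[1]], NULL, NULL)),
      active_site("f", "f_1", list(NULL, a$residues[[2]], NULL))),
    "no non-gap")
})
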