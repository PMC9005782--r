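## Synthetic fixture generation: idealized residue geometries, conformer
## ensembles with known ground-truth displacements, and multi-chain assembly
## structures (with ligands, interface sites and decoys) written in the same
## PDB/mmCIF/JSON formats the readers consume. Everything is driven by a
## single explicit seed, so fixtures are byte-identical across runs.

## Idealized local geometry per residue type: backbone (N, CA, C), CB where
## present, and the side-chain triad atoms. Internal coordinates are
## templated (chemically plausible bond lengths, non-collinear, residues are
## placed by rigid motion of the template); full rotamer realism is out of
## scope -- only the triad atoms plus backbone are needed downstream.
.residue_templates <- local({
  bb <- function(...) {
    rows <- list(...)
    data.frame(name = vapply(rows, `[[`, character(1), 1),
               x = vapply(rows, function(r) r[[2]][1], numeric(1)),
               y = vapply(rows, function(r) r[[2]][2], numeric(1)),
               z = vapply(rows, function(r) r[[2]][3], numeric(1)),
               stringsAsFactors = FALSE)
  }
  core <- list(list("N", c(-1.46, 0, 0)), list("CA", c(0, 0, 0)),
               list("C", c(0.53, 1.40, 0)))
  cb <- list(list("CB", c(0.60, -0.77, -1.20)))
  side <- list(
    ARG = list(list("CZ", c(0.60, -2.30, -4.30)),
               list("NH1", c(1.70, -2.90, -4.90)),
               list("NH2", c(-0.50, -2.70, -5.00))),
    LYS = list(list("CD", c(0.60, -1.60, -2.60)),
               list("CE", c(1.20, -2.40, -3.70)),
               list("NZ", c(1.20, -3.80, -3.50))),
    HIS = list(list("CG", c(0.60, -1.50, -2.30)),
               list("ND1", c(1.70, -2.10, -2.90)),
               list("CE1", c(1.40, -2.60, -4.10)),
               list("NE2", c(0.10, -2.40, -4.30))),
    ASP = list(list("CG", c(0.60, -1.60, -2.40)),
               list("OD1", c(1.60, -2.20, -2.90)),
               list("OD2", c(-0.50, -2.00, -2.90))),
    GLU = list(list("CG", c(0.60, -1.50, -2.50)),
               list("CD", c(0.60, -2.30, -3.70)),
               list("OE1", c(1.60, -2.90, -4.10)),
               list("OE2", c(-0.50, -2.50, -4.30))),
    SER = list(list("OG", c(0.10, -0.30, -2.45))),
    THR = list(list("OG1", c(0.10, -0.40, -2.40)),
               list("CG2", c(1.90, -1.20, -1.60))),
    CYS = list(list("SG", c(0.20, -0.40, -2.80))),
    TYR = list(list("CG", c(0.60, -1.50, -2.40)),
               list("CE1", c(0.90, -3.20, -3.70)),
               list("CZ", c(0.20, -3.70, -4.80)),
               list("OH", c(0.30, -4.90, -5.50))),
    ASN = list(list("CG", c(0.60, -1.60, -2.40)),
               list("OD1", c(1.60, -2.20, -2.90)),
               list("ND2", c(-0.50, -2.00, -2.90))),
    GLN = list(list("CG", c(0.60, -1.50, -2.50)),
               list("CD", c(0.60, -2.30, -3.70)),
               list("OE1", c(1.60, -2.90, -4.10)),
               list("NE2", c(-0.50, -2.50, -4.30))),
    TRP = list(list("CG", c(0.60, -1.50, -2.40)),
               list("CD1", c(1.80, -2.00, -2.80)),
               list("NE1", c(1.80, -2.80, -3.90)),
               list("CE2", c(0.50, -2.80, -4.30))),
    MET = list(list("CG", c(0.60, -1.50, -2.50)),
               list("SD", c(0.70, -2.50, -4.00)),
               list("CE", c(2.40, -2.90, -4.20))),
    PHE = list(list("CG", c(0.60, -1.50, -2.40)),
               list("CE1", c(0.90, -3.20, -3.70)),
               list("CZ", c(0.20, -3.70, -4.80)),
               list("CE2", c(-1.00, -3.00, -4.60))),
    VAL = list(list("CG1", c(1.90, -1.30, -1.70)),
               list("CG2", c(-0.60, -1.70, -1.90))),
    LEU = list(list("CG", c(0.60, -1.50, -2.50)),
               list("CD1", c(1.90, -2.20, -2.80)),
               list("CD2", c(-0.50, -2.30, -3.20))),
    ILE = list(list("CG1", c(1.90, -1.20, -1.70)),
               list("CD1", c(2.10, -2.30, -2.70))),
    ALA = list(), GLY = list(), PRO = list())
  out <- list()
  for (nm in names(side)) {
    rows <- c(core, if (nm != "GLY") cb, side[[nm]])
    out[[nm]] <- do.call(bb, rows)
  }
  out
})

#' Idealized residue template
#'
#' @param name 3-letter residue code present in the template library.
#' @return [atom_table()] of the template in local coordinates.
#' @export
residue_template <- function(name) {
  tpl <- .residue_templates[[toupper(name)]]
  assert_that(!is.null(tpl), sprintf("no residue template for '%s'", name))
  atom_table(name = tpl$name, x = tpl$x, y = tpl$y, z = tpl$z)
}

## place a residue template at a COM target with a given rotation
place_residue <- function(name, center, rotation) {
  atoms <- residue_template(name)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- apply_transform(xyz, rotation,
                         center - as.numeric(rotation %*% com3(xyz)))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

.ensemble_types <- c("ASP", "HIS", "ARG", "SER", "LYS", "GLU", "TYR", "ASN",
                     "THR", "LEU")
.ensemble_roles <- data.frame(
  role = c("proton acceptor", "proton shuttle", "electrostatic stabiliser",
           "nucleophile", "electrostatic stabiliser", "proton donor",
           "proton donor", "hydrogen bond donor", "nucleophile",
           "steric role"),
  category = c("reactant", "reactant", "spectator", "reactant", "spectator",
               "reactant", "reactant", "interaction", "reactant",
               "spectator"), stringsAsFactors = FALSE)

#' Specify a synthetic conformer ensemble
#'
#' Presets emulate the four family-level behaviours: `rigid` (isotropic
#' residue displacements, sigma 0.1 Angstrom), `flexible` (per-slot sigma
#' drawn uniformly from 0.5-1.5 Angstrom), `two_state` (two conformers:
#' half the slots shift coherently by `conformer_gap` in half the sites) and
#' `extensive` (random-walk drift of half the slots across the ensemble,
#' step `walk_step`). Setting `bound_fraction` instead emulates
#' ligand-driven stabilisation: bound sites perturbed with `sigma_bound`,
#' free sites with `sigma_free`.
#'
#' @param preset one of `"rigid"`, `"flexible"`, `"two_state"`,
#'   `"extensive"`.
#' @param n_sites number of homologous sites to generate (>= 2).
#' @param n_residues catalytic residues per site (<= 10).
#' @param sigma base isotropic noise (Angstrom); preset default if `NULL`.
#'   A vector of length `n_residues` fixes a per-slot noise level explicitly
#'   (e.g. to plant role-dependent flexibility), overriding the preset draw.
#' @param displaced_slots slots affected by the two-state shift / random
#'   walk; default: the first half.
#' @param conformer_gap two-state conformer separation (Angstrom).
#' @param walk_step random-walk step size (Angstrom).
#' @param bound_fraction optional fraction of ligand-bound sites.
#' @param sigma_bound,sigma_free per-site noise for bound/free sites when
#'   `bound_fraction` is set.
#' @param seed RNG seed.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(preset = c("rigid", "flexible", "two_state",
                                     "extensive"),
                          n_sites = 50, n_residues = 6, sigma = NULL,
                          displaced_slots = NULL, conformer_gap = 2.5,
                          walk_step = 1.0, bound_fraction = NULL,
                          sigma_bound = 0.1, sigma_free = 0.5, seed = 0) {
  preset <- match.arg(preset)
  assert_that(n_sites >= 2, "n_sites must be >= 2")
  assert_that(n_residues >= 2 && n_residues <= length(.ensemble_types),
              sprintf("n_residues must be in 2..%d", length(.ensemble_types)))
  sigma_provided <- !is.null(sigma)
  if (is.null(sigma)) sigma <- 0.1
  assert_that(all(sigma >= 0), "sigma must be >= 0")
  assert_that(length(sigma) == 1 || length(sigma) == n_residues,
              "sigma must be a scalar or one value per residue slot")
  if (is.null(displaced_slots)) {
    displaced_slots <- seq_len(ceiling(n_residues / 2))
  }
  structure(list(preset = preset, n_sites = n_sites,
                 n_residues = n_residues, sigma = sigma,
                 sigma_provided = sigma_provided,
                 displaced_slots = displaced_slots,
                 conformer_gap = conformer_gap, walk_step = walk_step,
                 bound_fraction = bound_fraction, sigma_bound = sigma_bound,
                 sigma_free = sigma_free, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a homologous-family conformer ensemble with known ground truth
#'
#' Builds an idealized reference site from the residue templates (residues on
#' a 5-Angstrom ring), then generates homologous sites as the reference plus
#' per-slot perturbations drawn from the preset, followed by a random rigid
#' motion of the whole site. All ground-truth displacements are recorded.
#'
#' @param spec an [ensemble_spec()].
#' @return a [family_annotation()] with atoms embedded in every site;
#'   attribute `"truth"` records the preset, per-site/per-slot displacement
#'   magnitudes, two-state state labels and bound flags.
#' @export
generate_site_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    nr <- spec$n_residues
    types <- .ensemble_types[seq_len(nr)]
    roles <- .ensemble_roles[seq_len(nr), ]
    angles <- 2 * pi * (seq_len(nr) - 1) / nr
    centers <- cbind(5 * cos(angles), 5 * sin(angles),
                     stats::runif(nr, -1, 1))
    rotations <- lapply(seq_len(nr), function(i) random_rotation())
    ref_residues <- lapply(seq_len(nr), function(s) {
      catalytic_residue(chain = "A", name = types[s], number = 10L * s,
                        function_location = "side_chain",
                        role = roles$role[s], role_category = roles$category[s],
                        equiv_group = 0L,
                        atoms = place_residue(types[s], centers[s, ],
                                              rotations[[s]]))
    })
    reference <- active_site(site_id = "ref", structure_id = "ref_1",
                             residues = ref_residues, is_reference = TRUE,
                             resolution = 1.5, experiment = "xray",
                             sequence_accession = "SYN00001")
    ## preset-specific slot parameters
    slot_sigma <- rep(spec$sigma, length.out = nr)
    if (spec$preset == "flexible" && is.null(spec$bound_fraction) &&
        !spec$sigma_provided) {
      slot_sigma <- stats::runif(nr, 0.5, 1.5)
    }
    gap_dirs <- matrix(0, nr, 3)
    if (spec$preset == "two_state") {
      for (s in spec$displaced_slots) {
        v <- stats::rnorm(3)
        gap_dirs[s, ] <- v / sqrt(sum(v^2)) * spec$conformer_gap
      }
    }
    walk <- matrix(0, nr, 3) # running random-walk offset per slot
    states <- rep(NA_character_, spec$n_sites)
    bound <- rep(NA, spec$n_sites)
    if (!is.null(spec$bound_fraction)) {
      bound <- stats::runif(spec$n_sites) < spec$bound_fraction
    }
    disp_mag <- matrix(0, spec$n_sites, nr)
    homologs <- vector("list", spec$n_sites)
    for (i in seq_len(spec$n_sites)) {
      if (spec$preset == "two_state") {
        states[i] <- if (stats::runif(1) < 0.5) "open" else "closed"
      }
      if (spec$preset == "extensive") {
        for (s in spec$displaced_slots) {
          walk[s, ] <- walk[s, ] + stats::rnorm(3, sd = spec$walk_step)
        }
      }
      site_sigma <- slot_sigma
      if (!is.null(spec$bound_fraction)) {
        site_sigma <- rep(if (bound[i]) spec$sigma_bound else spec$sigma_free,
                          nr)
      }
      R <- random_rotation()
      tr <- stats::runif(3, -20, 20)
      residues <- vector("list", nr)
      for (s in seq_len(nr)) {
        d <- stats::rnorm(3, sd = site_sigma[s])
        if (spec$preset == "two_state" && states[i] == "closed") {
          d <- d + gap_dirs[s, ]
        }
        if (spec$preset == "extensive" && s %in% spec$displaced_slots) {
          d <- d + walk[s, ]
        }
        disp_mag[i, s] <- sqrt(sum(d^2))
        atoms <- ref_residues[[s]]$atoms
        xyz <- as.matrix(atoms[, c("x", "y", "z")])
        xyz <- xyz + matrix(d, nrow(xyz), 3, byrow = TRUE)
        xyz <- apply_transform(xyz, R, tr)
        atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
        residues[[s]] <- catalytic_residue(
          chain = "A", name = types[s], number = 10L * s,
          function_location = "side_chain", role = roles$role[s],
          role_category = roles$category[s], equiv_group = 0L, atoms = atoms)
      }
      homologs[[i]] <- active_site(
        site_id = sprintf("hom%03d", i),
        structure_id = sprintf("hom%03d_1", i), residues = residues,
        resolution = round(stats::runif(1, 1.0, 2.0), 2),
        experiment = "xray", sequence_accession = "SYN00001")
    }
    fam <- family_annotation(
      family_id = sprintf("SYN_%s", spec$preset), reference = reference,
      homologs = homologs, ec_number = "1.1.1.1")
    attr(fam, "truth") <- list(preset = spec$preset,
                               displacement = disp_mag, states = states,
                               bound = bound, slot_sigma = slot_sigma,
                               displaced_slots = spec$displaced_slots)
    fam
  })
}

## deterministic blob coordinates for a small molecule centred at `center`
molecule_coordinates <- function(mol, center) {
  n <- length(mol$elements)
  pos <- matrix(0, n, 3)
  if (n > 1) {
    for (k in 2:n) {
      step <- stats::rnorm(3)
      pos[k, ] <- pos[k - 1, ] + step / sqrt(sum(step^2)) * 1.45
    }
  }
  pos <- pos - matrix(com3(pos), n, 3, byrow = TRUE) +
    matrix(center, n, 3, byrow = TRUE)
  atom_table(name = paste0(mol$elements, seq_len(n)),
             element = mol$elements, x = pos[, 1], y = pos[, 2],
             z = pos[, 3])
}

#' Generate a synthetic multi-chain assembly with annotation and ligands
#'
#' Builds a structure exercising the site-reconstruction and
#' ligand-annotation stages, writes PDB, mmCIF and annotation JSON
#' renderings, and returns the in-memory objects.
#'
#' Layouts: `"homodimer"` -- two chains, each carrying the full Ser-His-Asp
#' catalytic set in spatially separated copies (expected: two single-chain
#' sites); `"interface"` -- one C2-symmetric site straddling both chains,
#' each contributing an Asp25/Thr26 pair distinguished by equivalence groups
#' (expected: one multi-chain site).
#'
#' @param layout `"homodimer"` or `"interface"`.
#' @param ligands list of placements: each a list with `comp_id` and
#'   `offset` (3-vector relative to each site centroid).
#' @param decoy mis-number the first catalytic residue of chain A to a
#'   position 40 Angstrom away, so the site built from it violates the
#'   3x-reference sanity rule.
#' @param molecules molecule library for ligand coordinates.
#' @param seed RNG seed.
#' @param dir output directory for the PDB/mmCIF/JSON files (`NULL`: no
#'   files written).
#' @return list with `struct` ([structure3d()]), `family`
#'   ([family_annotation()] whose reference carries coordinates), `paths`
#'   (written files) and `expected_sites`.
#' @export
generate_assembly <- function(layout = c("homodimer", "interface"),
                              ligands = list(), decoy = FALSE,
                              molecules = default_molecules(), seed = 0,
                              dir = NULL) {
  layout <- match.arg(layout)
  with_seed(seed, {
    if (layout == "homodimer") {
      defs <- data.frame(name = c("SER", "HIS", "ASP"),
                         number = c(10L, 20L, 30L), equiv = c(0L, 0L, 0L),
                         stringsAsFactors = FALSE)
      roles <- data.frame(role = c("nucleophile", "proton shuttle",
                                   "electrostatic stabiliser"),
                          category = c("reactant", "reactant", "spectator"),
                          stringsAsFactors = FALSE)
      angles <- 2 * pi * (0:2) / 3
      local_centers <- cbind(4.5 * cos(angles), 4.5 * sin(angles), 0)
      chain_shift <- list(A = c(0, 0, 0), B = c(40, 0, 0))
      chain_for_slot <- list(A = 1:3, B = 1:3)
      expected_sites <- 2L
    } else {
      defs <- data.frame(name = c("ASP", "THR", "ASP", "THR"),
                         number = c(25L, 26L, 25L, 26L),
                         equiv = c(0L, 0L, 1L, 1L), stringsAsFactors = FALSE)
      roles <- data.frame(role = rep(c("proton acceptor",
                                       "hydrogen bond donor"), 2),
                          category = rep(c("reactant", "interaction"), 2),
                          stringsAsFactors = FALSE)
      ## C2 symmetry about z through the origin
      local_centers <- rbind(c(3.0, 1.5, 0.8), c(4.5, -1.0, -0.5),
                             c(-3.0, -1.5, 0.8), c(-4.5, 1.0, -0.5))
      chain_shift <- list(A = c(0, 0, 0), B = c(0, 0, 0))
      chain_for_slot <- list(A = 1:2, B = 3:4)
      expected_sites <- 1L
    }
    nslot <- nrow(defs)
    rows <- list()
    ref_residues <- vector("list", nslot)
    add_atoms <- function(atoms, type, chain, resno, resid) {
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, chain = chain, resno = resno, resid = resid,
        elety = atoms$name, element = atoms$element, x = atoms$x,
        y = atoms$y, z = atoms$z, occupancy = atoms$occupancy,
        altloc = atoms$altloc, stringsAsFactors = FALSE)
    }
    site_centroids <- list()
    for (ch in c("A", "B")) {
      slots <- chain_for_slot[[ch]]
      placed <- list()
      for (s in slots) {
        center <- local_centers[s, ] + chain_shift[[ch]]
        rot <- random_rotation()
        true_atoms <- place_residue(defs$name[s], center, rot)
        atoms <- true_atoms
        if (decoy && ch == "A" && s == slots[1]) {
          ## mis-numbered residue placed far away in the structure; the
          ## manually curated reference keeps the true geometry
          atoms <- place_residue(defs$name[s], center + c(0, 40, 0), rot)
        }
        add_atoms(atoms, "ATOM", ch, defs$number[s], defs$name[s])
        placed[[as.character(s)]] <- true_atoms
        if (ch == "A") {
          ref_residues[[s]] <- catalytic_residue(
            chain = "A", name = defs$name[s], number = defs$number[s],
            function_location = "side_chain", role = roles$role[s],
            role_category = roles$category[s], equiv_group = defs$equiv[s],
            atoms = true_atoms)
        }
      }
      ## scaffold polymer context (GLY stretch away from the site)
      for (k in 1:4) {
        center <- chain_shift[[ch]] + c(10 + 1.8 * k, 6, 2)
        atoms <- place_residue("GLY", center, random_rotation())
        add_atoms(atoms, "ATOM", ch, 50L + k, "GLY")
      }
      site_centroids[[ch]] <- com3(do.call(rbind, lapply(placed, function(a) {
        as.matrix(a[, c("x", "y", "z")])
      })))
    }
    if (layout == "interface") {
      ## reference spans both chains; fill the equiv-1 slots from chain B
      b_rows <- do.call(rbind, rows)
      for (s in chain_for_slot$B) {
        sel <- b_rows$chain == "B" & b_rows$resno == defs$number[s] &
          b_rows$resid == defs$name[s]
        sub <- b_rows[sel, , drop = FALSE]
        ref_residues[[s]] <- catalytic_residue(
          chain = "B", name = defs$name[s], number = defs$number[s],
          function_location = "side_chain", role = roles$role[s],
          role_category = roles$category[s], equiv_group = defs$equiv[s],
          atoms = atom_table(name = sub$elety, element = sub$element,
                             x = sub$x, y = sub$y, z = sub$z))
      }
      site_centroids <- list(A = com3(do.call(rbind,
        lapply(ref_residues, function(r) residue_xyz(r)))))
    }
    ## ligand placements relative to each site centroid
    lig_no <- 900L
    for (centroid in site_centroids) {
      for (pl in ligands) {
        mol <- molecules[[toupper(pl$comp_id)]]
        assert_that(!is.null(mol),
                    sprintf("no molecule definition for '%s'", pl$comp_id))
        atoms <- molecule_coordinates(mol, centroid + pl$offset)
        add_atoms(atoms, "HETATM", "X", lig_no, mol$comp_id)
        lig_no <- lig_no + 1L
      }
    }
    atoms <- do.call(rbind, rows)
    struct <- structure3d(atoms, structure_id = sprintf("syn_%s_1", layout))
    reference <- active_site(site_id = "ref", structure_id = struct$structure_id,
                             residues = ref_residues, is_reference = TRUE,
                             resolution = 1.5, experiment = "xray",
                             sequence_accession = "SYN00002")
    family <- family_annotation(
      family_id = sprintf("SYN_%s", toupper(layout)), reference = reference,
      homologs = list(), ec_number = "3.4.21.1")
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(
        pdb = file.path(dir, paste0(struct$structure_id, ".pdb")),
        cif = file.path(dir, paste0(struct$structure_id, ".cif")),
        annotation = file.path(dir, paste0(family$family_id, ".json")))
      write_structure_pdb(struct, paths$pdb)
      write_structure_cif(struct, paths$cif)
      save_family_annotation(family, paths$annotation)
    }
    list(struct = struct, family = family, paths = paths,
         expected_sites = expected_sites)
  })
}
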