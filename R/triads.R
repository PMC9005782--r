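## Functional atom triads: for each catalytic residue, the three atoms of the
## moiety that performs its catalytic function. Side-chain triads follow the
## chemistry of the functional group (Arg anchored by its three endpoint
## guanidino atoms CZ/NH1/NH2); residues functioning via the main chain, or
## carrying post-translational modifications, use (N, CA, C). `sym` lists
## groups of triad positions that are mutually exchangeable because the
## underlying atoms cannot be distinguished in electron density (terminal
## carboxylate oxygens, His ring atoms, aromatic/aliphatic symmetric pairs).

.default_triads <- list(
  ARG = list(atoms = c("CZ", "NH1", "NH2"), sym = list(c(2L, 3L))),
  LYS = list(atoms = c("CD", "CE", "NZ"),   sym = list()),
  HIS = list(atoms = c("ND1", "CE1", "NE2"), sym = list(c(1L, 2L, 3L))),
  ASP = list(atoms = c("CG", "OD1", "OD2"), sym = list(c(2L, 3L))),
  GLU = list(atoms = c("CD", "OE1", "OE2"), sym = list(c(2L, 3L))),
  SER = list(atoms = c("CA", "CB", "OG"),   sym = list()),
  THR = list(atoms = c("CA", "CB", "OG1"),  sym = list()),
  CYS = list(atoms = c("CA", "CB", "SG"),   sym = list()),
  TYR = list(atoms = c("CE1", "CZ", "OH"),  sym = list()),
  ASN = list(atoms = c("CG", "OD1", "ND2"), sym = list()),
  GLN = list(atoms = c("CD", "OE1", "NE2"), sym = list()),
  TRP = list(atoms = c("CD1", "NE1", "CE2"), sym = list()),
  MET = list(atoms = c("CG", "SD", "CE"),   sym = list()),
  PHE = list(atoms = c("CE1", "CZ", "CE2"), sym = list(c(1L, 3L))),
  VAL = list(atoms = c("CB", "CG1", "CG2"), sym = list(c(2L, 3L))),
  LEU = list(atoms = c("CG", "CD1", "CD2"), sym = list(c(2L, 3L))),
  ILE = list(atoms = c("CB", "CG1", "CD1"), sym = list()),
  ALA = list(atoms = c("N", "CA", "C"),     sym = list()),
  GLY = list(atoms = c("N", "CA", "C"),     sym = list()),
  PRO = list(atoms = c("N", "CA", "C"),     sym = list())
)

.main_chain_triad <- list(atoms = c("N", "CA", "C"), sym = list())

## Conservative mutation equivalence sets: mismatches within one set are
## handled by pairing the chemically analogous triad atoms positionally.
.conservative_sets <- list(
  c("ASP", "GLU"),
  c("ASN", "GLN"),
  c("SER", "THR", "TYR"),
  c("VAL", "LEU", "ILE")
)

#' Default functional-atom triad table
#'
#' @return named list: per residue type, `atoms` (three atom names, listed
#'   inner-to-outer so that conservative mismatches pair positionally) and
#'   `sym` (list of integer vectors of mutually exchangeable positions).
#' @export
triad_table <- function() .default_triads

#' Select the functional atom triad of a catalytic residue
#'
#' Side-chain residues use the triad table; residues functioning via the main
#' chain or subject to post-translational modification (and residue types
#' absent from the table, e.g. modified residues) use the main-chain triad
#' (N, CA, C).
#'
#' @param residue a [catalytic_residue()] with coordinates.
#' @param table triad table (see [triad_table()]); entries are
#'   config-overridable.
#' @return list of class `functional_triad` with `atom_names`,
#'   `symmetry_classes` (list of exchangeable position groups), `source`
#'   (`"side_chain"` or `"main_chain"`), and `xyz` (3 x 3 coordinates); or
#'   `NULL` with a warning if a required atom is missing from the
#'   coordinates (the slot is then treated as a gap).
#' @export
functional_triad <- function(residue, table = triad_table()) {
  use_main <- residue$function_location %in% c("main_chain",
                                               "post_translational") ||
    !(residue$name %in% names(table))
  def <- if (use_main) .main_chain_triad else table[[residue$name]]
  idx <- match(def$atoms, residue$atoms$name)
  if (anyNA(idx)) {
    warning(sprintf("residue %s %s%d: triad atom(s) %s missing; slot demoted to gap",
                    residue$chain, residue$name, residue$number,
                    paste(def$atoms[is.na(idx)], collapse = ",")),
            call. = FALSE)
    return(NULL)
  }
  structure(list(atom_names = def$atoms,
                 symmetry_classes = def$sym,
                 source = if (use_main) "main_chain" else "side_chain",
                 xyz = residue_xyz(residue)[idx, , drop = FALSE]),
            class = "functional_triad")
}

## merge possibly-overlapping position groups into disjoint classes
merge_sym_groups <- function(groups) {
  if (!length(groups)) return(list())
  out <- list()
  for (g in groups) {
    hit <- which(vapply(out, function(o) any(o %in% g), logical(1)))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(out[hit]), g)))
      out <- c(out[-hit], list(merged))
    } else {
      out <- c(out, list(sort(unique(g))))
    }
  }
  out
}

#' Pair the residues of two positionally aligned active sites
#'
#' Classifies each slot as a `match` (same residue type), a
#' `conservative_mismatch` (within the equivalence sets Asp-Glu, Asn-Gln,
#' Ser-Thr-Tyr, Val-Leu-Ile, paired over chemically analogous triad atoms), a
#' `nonequivalent_mismatch` (all three triad atoms treated as mutually
#' exchangeable pseudo-mutations), or a `gap` (either side null or triad
#' unavailable; excluded from superposition entirely).
#'
#' @param site_a,site_b positionally aligned [active_site()] objects.
#' @param table triad table.
#' @return list of per-slot pairings, each with `slot`, `kind`,
#'   `atoms_a`/`atoms_b` (names), `xyz_a`/`xyz_b` (3 x 3), and
#'   `symmetry_classes` (exchangeable triad positions for this pair).
#' @export
pair_residues <- function(site_a, site_b, table = triad_table()) {
  n <- length(site_a$residues)
  assert_that(length(site_b$residues) == n,
              "sites must be positionally aligned (equal slot counts)")
  out <- vector("list", n)
  for (s in seq_len(n)) {
    ra <- site_a$residues[[s]]
    rb <- site_b$residues[[s]]
    if (is.null(ra) || is.null(rb)) {
      out[[s]] <- list(slot = s, kind = "gap")
      next
    }
    ta <- functional_triad(ra, table)
    tb <- functional_triad(rb, table)
    if (is.null(ta) || is.null(tb)) {
      out[[s]] <- list(slot = s, kind = "gap")
      next
    }
    if (ra$name == rb$name) {
      kind <- "match"
      sym <- ta$symmetry_classes
    } else if (any(vapply(.conservative_sets,
                          function(set) all(c(ra$name, rb$name) %in% set),
                          logical(1)))) {
      kind <- "conservative_mismatch"
      sym <- merge_sym_groups(c(ta$symmetry_classes, tb$symmetry_classes))
    } else {
      kind <- "nonequivalent_mismatch"
      sym <- list(1:3)
    }
    out[[s]] <- list(slot = s, kind = kind,
                     atoms_a = ta$atom_names, atoms_b = tb$atom_names,
                     xyz_a = ta$xyz, xyz_b = tb$xyz,
                     symmetry_classes = sym)
  }
  out
}
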