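## Structure I/O. Structures are held as a flat atom table (one row per
## atom), the canonical coordinate convention for the whole package:
## Cartesian Angstrom, author residue numbering as in the source file.

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `chain`,
#'   `resno`, `resid` (3-letter component code), `elety` (atom name),
#'   `element`, `x`, `y`, `z`, `occupancy`, `altloc`.
#' @param structure_id identifier (PDB id + assembly index).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, structure_id = "struct_1") {
  needed <- c("type", "chain", "resno", "resid", "elety", "element",
              "x", "y", "z", "occupancy", "altloc")
  missing <- setdiff(needed, names(atoms))
  assert_that(length(missing) == 0,
              paste("atom table missing columns:",
                    paste(missing, collapse = ", ")))
  atoms$het <- atoms$type == "HETATM" | !(atoms$resid %in% .standard_aa)
  structure(list(atoms = atoms, structure_id = structure_id),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d %s> %d atoms, %d chains, %d hetero atoms\n",
              x$structure_id, nrow(x$atoms), length(unique(x$atoms$chain)),
              sum(x$atoms$het)))
  invisible(x)
}

## Keep the highest-occupancy alternate conformer per atom, ties broken
## alphabetically by altloc. Single-conformer coordinates are required by
## the superposition math.
apply_altloc_policy <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid,
                                   atoms$elety, sep = "|")), , drop = FALSE]
  atoms[order(atoms$chain, atoms$resno, atoms$elety), , drop = FALSE]
}

#' Load a structure from a PDB or mmCIF file
#'
#' Reads coordinates in Angstrom with author residue numbering preserved.
#' Alternate locations are reduced to the highest-occupancy conformer (ties
#' broken alphabetically); hydrogens (and deuteriums) are dropped; for
#' multi-model PDB files the `assembly` argument selects the MODEL block.
#'
#' @param path mmCIF (`.cif`) or PDB file.
#' @param assembly 1-based model/assembly index within the file.
#' @return a [structure3d()] object.
#' @export
load_structure <- function(path, assembly = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("structure file not found: %s", path), call. = FALSE)
  }
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    if (assembly != 1L) {
      stop(sprintf("assembly index %d not present in %s (mmCIF loader reads model 1 only)",
                   assembly, path), call. = FALSE)
    }
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  }
  at <- pdb$atom
  if (!is_cif) {
    nmod <- nrow(pdb$xyz)
    if (assembly < 1L || assembly > nmod) {
      stop(sprintf("assembly index %d not present in %s (%d model(s))",
                   assembly, path, nmod), call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[assembly, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element <- ifelse(is.na(element) | !nzchar(element),
                    guess_element(at$elety), element)
  atoms <- data.frame(type = at$type, chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      element = toupper(element),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
                      stringsAsFactors = FALSE)
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- apply_altloc_policy(atoms)
  sid <- paste0(sub("\\.(pdb|ent|cif)$", "", basename(path),
                    ignore.case = TRUE), "_", assembly)
  structure3d(atoms, structure_id = sid)
}

#' Write a structure to a PDB file
#'
#' @param struct a [structure3d()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  a <- struct$atoms
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(n), elety = a$elety, chain = a$chain,
                   alt = ifelse(nzchar(a$altloc), a$altloc, NA),
                   o = a$occupancy, b = rep(0, n), elesy = a$element)
  invisible(path)
}

#' Write a structure to a minimal mmCIF file
#'
#' Emits a single `_atom_site` loop (the subset of the mmCIF dictionary
#' needed to round-trip coordinates, names and numbering through standard
#' readers).
#'
#' @param struct a [structure3d()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(struct, path) {
  a <- struct$atoms
  n <- nrow(a)
  hdr <- c(sprintf("data_%s", struct$structure_id),
           "#",
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.id",
           "_atom_site.type_symbol",
           "_atom_site.label_atom_id",
           "_atom_site.label_alt_id",
           "_atom_site.label_comp_id",
           "_atom_site.label_asym_id",
           "_atom_site.label_entity_id",
           "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  alt <- ifelse(nzchar(a$altloc), a$altloc, ".")
  rows <- sprintf("%-6s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
                  a$type, seq_len(n), a$element, a$elety, alt, a$resid,
                  a$chain, a$resno, a$x, a$y, a$z, a$occupancy, a$resno,
                  a$resid, a$chain, a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

## atoms of one polymer/hetero residue instance as an atom_table data frame
instance_atoms <- function(struct, chain, resno, resid = NULL) {
  a <- struct$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!is.null(resid)) sel <- sel & a$resid == resid
  sub <- a[sel, , drop = FALSE]
  atom_table(name = sub$elety, element = sub$element,
             x = sub$x, y = sub$y, z = sub$z,
             occupancy = sub$occupancy, altloc = sub$altloc)
}
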