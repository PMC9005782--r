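## S3 constructors and validators for the package's core domain objects.
## Atoms are stored as plain data frames (one row per atom) with columns
## name, element, x, y, z, occupancy, altloc -- all coordinates in Angstrom.

.valid_locations <- c("main_chain", "side_chain", "post_translational")
.valid_categories <- c("reactant", "interaction", "spectator")
.valid_experiments <- c("xray", "nmr", "em", "synthetic")

#' Build an atom table
#'
#' @param name character vector of PDB-convention atom names (e.g. "CZ").
#' @param element element symbols; derived from `name` when missing.
#' @param x,y,z coordinates in Angstrom.
#' @param occupancy occupancies in `[0, 1]`.
#' @param altloc alternate-location indicators ("" = none).
#' @return data.frame with one row per atom.
#' @export
atom_table <- function(name, element = NULL, x, y, z,
                       occupancy = 1, altloc = "") {
  if (is.null(element)) element <- guess_element(name)
  df <- data.frame(name = as.character(name), element = as.character(element),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   occupancy = as.numeric(occupancy),
                   altloc = as.character(altloc),
                   stringsAsFactors = FALSE)
  assert_that(all(is.finite(df$x)) && all(is.finite(df$y)) &&
                all(is.finite(df$z)), "atom coordinates must be finite")
  assert_that(all(nzchar(df$element)), "atom elements must be non-empty")
  df
}

#' Create a catalytic residue
#'
#' One annotated catalytic residue: identity, chain, where its function is
#' located (main chain / side chain / post-translational), its mechanistic
#' role, and an equivalence-group id distinguishing otherwise identical
#' residues contributed by symmetric subunits to one interface site.
#'
#' @param chain chain identifier.
#' @param name 3-letter residue code.
#' @param number author residue number (as in the source file).
#' @param function_location one of `"main_chain"`, `"side_chain"`,
#'   `"post_translational"`.
#' @param role free-text role label (e.g. "proton donor").
#' @param role_category one of `"reactant"`, `"interaction"`, `"spectator"`.
#' @param equiv_group non-negative integer equivalence-group id.
#' @param atoms optional atom table (see [atom_table()]).
#' @return object of class `catalytic_residue`.
#' @export
catalytic_residue <- function(chain, name, number,
                              function_location = "side_chain",
                              role = "", role_category = "spectator",
                              equiv_group = 0L, atoms = NULL) {
  assert_that(is.character(name) && nchar(name) >= 1,
              "residue name must be a residue code string")
  assert_that(function_location %in% .valid_locations,
              paste("function_location must be one of:",
                    paste(.valid_locations, collapse = ", ")))
  assert_that(role_category %in% .valid_categories,
              paste("role_category must be one of:",
                    paste(.valid_categories, collapse = ", ")))
  assert_that(equiv_group >= 0, "equiv_group must be >= 0")
  structure(list(chain = as.character(chain), name = toupper(name),
                 number = as.integer(number),
                 function_location = function_location,
                 role = role, role_category = role_category,
                 equiv_group = as.integer(equiv_group), atoms = atoms),
            class = "catalytic_residue")
}

#' Create an active site
#'
#' An ordered collection of catalytic residues from one assembly, aligned
#' positionally (1:1, gaps as `NULL` slots) to the family reference site.
#'
#' @param site_id site identifier.
#' @param structure_id source structure identifier (PDB id + assembly index).
#' @param residues list of [catalytic_residue()] objects or `NULL` gaps.
#' @param is_reference is this the family reference site?
#' @param resolution resolution in Angstrom, or `NA`.
#' @param experiment one of `"xray"`, `"nmr"`, `"em"`, `"synthetic"`.
#' @param sequence_accession sequence accession used for same-protein checks.
#' @return object of class `active_site`.
#' @export
active_site <- function(site_id, structure_id, residues,
                        is_reference = FALSE, resolution = NA_real_,
                        experiment = "xray",
                        sequence_accession = NA_character_) {
  assert_that(is.list(residues) && length(residues) >= 1,
              "residues must be a non-empty list")
  filled <- !vapply(residues, is.null, logical(1))
  assert_that(any(filled), "active site needs at least one non-null residue")
  for (r in residues[filled]) {
    assert_that(inherits(r, "catalytic_residue"),
                "residues must be catalytic_residue objects or NULL")
  }
  assert_that(experiment %in% .valid_experiments,
              paste("experiment must be one of:",
                    paste(.valid_experiments, collapse = ", ")))
  chains <- unique(vapply(residues[filled], `[[`, character(1), "chain"))
  structure(list(site_id = as.character(site_id),
                 structure_id = as.character(structure_id),
                 residues = residues, is_reference = isTRUE(is_reference),
                 is_multichain = length(chains) >= 2,
                 resolution = as.numeric(resolution), experiment = experiment,
                 sequence_accession = as.character(sequence_accession)),
            class = "active_site")
}

#' Create a family annotation
#'
#' A reference active site with manually annotated catalytic residues plus
#' the homologous sites positionally aligned to it.
#'
#' @param family_id family identifier.
#' @param reference reference [active_site()] (`is_reference` must be TRUE).
#' @param homologs list of positionally aligned homologous sites.
#' @param ec_number EC number string or `NULL`.
#' @return object of class `family_annotation`.
#' @export
family_annotation <- function(family_id, reference, homologs = list(),
                              ec_number = NULL) {
  assert_that(inherits(reference, "active_site"),
              "reference must be an active_site")
  assert_that(reference$is_reference,
              "reference site must have is_reference = TRUE")
  nref <- length(reference$residues)
  for (h in homologs) {
    assert_that(inherits(h, "active_site"),
                "homologs must be active_site objects")
    assert_that(length(h$residues) == nref,
                sprintf("homolog site '%s' is not aligned to the reference (%d slots, reference has %d)",
                        h$site_id, length(h$residues), nref))
  }
  structure(list(family_id = as.character(family_id), reference = reference,
                 homologs = homologs, ec_number = ec_number),
            class = "family_annotation")
}

#' Create a small-molecule definition
#'
#' Minimal element + bond-list chemistry used by the chemical similarity
#' score: no coordinates, no bond-order semantics beyond bookkeeping.
#'
#' @param comp_id 3-letter component code.
#' @param elements character vector of element symbols, one per atom.
#' @param bonds integer matrix with columns (i, j, order), 1-based indices;
#'   may have zero rows for single atoms.
#' @return object of class `small_molecule`.
#' @export
small_molecule <- function(comp_id, elements, bonds = NULL) {
  n <- length(elements)
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(0), 0, 3)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3)
  }
  colnames(bonds) <- c("i", "j", "order")
  if (nrow(bonds)) {
    assert_that(all(bonds[, 1:2] >= 1) && all(bonds[, 1:2] <= n),
                "bond indices out of range")
    assert_that(all(bonds[, 1] != bonds[, 2]), "self-loop bond not allowed")
  }
  structure(list(comp_id = toupper(comp_id),
                 elements = toupper(as.character(elements)), bonds = bonds),
            class = "small_molecule")
}

## ---- small accessors used throughout -------------------------------------

## coordinates of a residue's atoms as an n x 3 matrix
residue_xyz <- function(res) {
  as.matrix(res$atoms[, c("x", "y", "z")])
}

## centre of mass (all heavy atoms, unit masses) of a residue
residue_com <- function(res) com3(residue_xyz(res))

## non-null residue slots of a site
filled_slots <- function(site) {
  which(!vapply(site$residues, is.null, logical(1)))
}

## all atom coordinates of a site (filled slots only)
site_xyz <- function(site) {
  do.call(rbind, lapply(site$residues[filled_slots(site)], residue_xyz))
}

## mean inter-residue COM distance of a site (NA if < 2 filled slots)
mean_intra_distance <- function(site) {
  idx <- filled_slots(site)
  if (length(idx) < 2) return(NA_real_)
  coms <- t(vapply(site$residues[idx], residue_com, numeric(3)))
  mean(stats::dist(coms))
}

#' @export
print.active_site <- function(x, ...) {
  filled <- filled_slots(x)
  cat(sprintf("<active_site %s> structure %s: %d/%d slots filled%s%s\n",
              x$site_id, x$structure_id, length(filled), length(x$residues),
              if (x$is_multichain) ", multi-chain" else "",
              if (x$is_reference) ", reference" else ""))
  for (i in filled) {
    r <- x$residues[[i]]
    cat(sprintf("  [%d] %s %s%d (%s, %s, equiv %d)\n", i, r$chain, r$name,
                r$number, r$function_location, r$role_category, r$equiv_group))
  }
  invisible(x)
}

#' @export
print.family_annotation <- function(x, ...) {
  cat(sprintf("<family_annotation %s> %d reference slots, %d homologous sites%s\n",
              x$family_id, length(x$reference$residues), length(x$homologs),
              if (!is.null(x$ec_number)) paste0(", EC ", x$ec_number) else ""))
  invisible(x)
}

#' @export
print.small_molecule <- function(x, ...) {
  cat(sprintf("<small_molecule %s> %d atoms (%s), %d bonds\n", x$comp_id,
              length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = "/"),
              nrow(x$bonds)))
  invisible(x)
}
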