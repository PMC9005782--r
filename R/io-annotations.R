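## Catalytic-residue annotation files: a versioned JSON dialect modelled on
## curated catalytic-site database exports. One file holds one homologous
## family: a reference site whose catalytic residues are manually annotated,
## plus homologous sites positionally aligned to it (gaps as nulls). Residues
## may embed atom coordinates, making a family file fully self-contained.

.annotation_schema_version <- "1.0"

res_to_list <- function(r) {
  if (is.null(r)) return(NULL)
  out <- list(chain = r$chain, name = r$name, number = r$number,
              function_location = r$function_location, role = r$role,
              role_category = r$role_category, equiv_group = r$equiv_group)
  if (!is.null(r$atoms)) {
    out$atoms <- lapply(seq_len(nrow(r$atoms)), function(i) {
      a <- r$atoms[i, ]
      list(name = a$name, element = a$element,
           xyz = c(a$x, a$y, a$z), occupancy = a$occupancy,
           altloc = a$altloc)
    })
  }
  out
}

site_to_list <- function(s) {
  list(site_id = s$site_id, structure_id = s$structure_id,
       is_reference = s$is_reference, resolution = s$resolution,
       experiment = s$experiment,
       sequence_accession = s$sequence_accession,
       residues = lapply(s$residues, res_to_list))
}

schema_stop <- function(key, why) {
  stop(sprintf("annotation schema error at '%s': %s", key, why),
       call. = FALSE)
}

res_from_list <- function(x, key) {
  if (is.null(x)) return(NULL)
  for (f in c("chain", "name", "number", "function_location",
              "role_category", "equiv_group")) {
    if (is.null(x[[f]])) schema_stop(paste0(key, ".", f), "missing field")
  }
  atoms <- NULL
  if (!is.null(x$atoms)) {
    atoms <- atom_table(
      name = vapply(x$atoms, `[[`, character(1), "name"),
      element = vapply(x$atoms, `[[`, character(1), "element"),
      x = vapply(x$atoms, function(a) a$xyz[[1]], numeric(1)),
      y = vapply(x$atoms, function(a) a$xyz[[2]], numeric(1)),
      z = vapply(x$atoms, function(a) a$xyz[[3]], numeric(1)),
      occupancy = vapply(x$atoms, function(a) a$occupancy %||% 1, numeric(1)),
      altloc = vapply(x$atoms, function(a) a$altloc %||% "", character(1)))
  }
  catalytic_residue(chain = x$chain, name = x$name, number = x$number,
                    function_location = x$function_location,
                    role = x$role %||% "",
                    role_category = x$role_category,
                    equiv_group = x$equiv_group, atoms = atoms)
}

site_from_list <- function(x, key, is_reference = FALSE) {
  for (f in c("site_id", "structure_id", "residues")) {
    if (is.null(x[[f]])) schema_stop(paste0(key, ".", f), "missing field")
  }
  residues <- lapply(seq_along(x$residues), function(i) {
    res_from_list(x$residues[[i]], sprintf("%s.residues[%d]", key, i))
  })
  active_site(site_id = x$site_id, structure_id = x$structure_id,
              residues = residues,
              is_reference = x$is_reference %||% is_reference,
              resolution = x$resolution %||% NA_real_,
              experiment = x$experiment %||% "xray",
              sequence_accession = x$sequence_accession %||% NA_character_)
}

#' Load a family annotation file
#'
#' @param path JSON annotation file (see the package's annotation dialect:
#'   versioned schema with `family_id`, `ec_number`, `reference` site and
#'   positionally aligned `homologs`).
#' @return a [family_annotation()] object.
#' @export
load_family_annotation <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
                  stop(sprintf("malformed JSON in %s: %s", path,
                               conditionMessage(e)), call. = FALSE)
                })
  if (is.null(x$reference)) schema_stop("reference", "reference site missing")
  if (is.null(x$family_id)) schema_stop("family_id", "missing field")
  reference <- site_from_list(x$reference, "reference", is_reference = TRUE)
  nref <- length(reference$residues)
  homologs <- lapply(seq_along(x$homologs %||% list()), function(i) {
    key <- sprintf("homologs[%d]", i)
    h <- site_from_list(x$homologs[[i]], key)
    if (length(h$residues) != nref) {
      schema_stop(paste0(key, ".residues"),
                  sprintf("%d slots but reference has %d (homolog not aligned to reference)",
                          length(h$residues), nref))
    }
    h
  })
  family_annotation(family_id = x$family_id, reference = reference,
                    homologs = homologs, ec_number = x$ec_number)
}

#' Save a family annotation file
#'
#' Writes the versioned JSON annotation dialect; [load_family_annotation()]
#' of the result reproduces the input exactly.
#'
#' @param family a [family_annotation()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_family_annotation <- function(family, path) {
  x <- list(schema_version = .annotation_schema_version,
            family_id = family$family_id,
            ec_number = family$ec_number,
            reference = site_to_list(family$reference),
            homologs = lapply(family$homologs, site_to_list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Load small-molecule definitions
#'
#' @param path JSON file: array of objects with `comp_id`, `atoms` (array of
#'   `{element}`) and `bonds` (array of `[i, j, order]`, 1-based).
#' @return named list of [small_molecule()] objects.
#' @export
load_molecules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mols <- lapply(x, function(m) {
    if (is.null(m$comp_id)) schema_stop("comp_id", "missing field")
    bonds <- if (length(m$bonds)) {
      do.call(rbind, lapply(m$bonds, function(b) as.integer(unlist(b))))
    }
    small_molecule(comp_id = m$comp_id,
                   elements = vapply(m$atoms, `[[`, character(1), "element"),
                   bonds = bonds)
  })
  names(mols) <- vapply(mols, `[[`, character(1), "comp_id")
  mols
}

#' Load a component code table (cofactors or crystallisation artefacts)
#'
#' @param path two-column TSV (`comp_id`, `label`), `#` comments allowed.
#' @return character vector of component codes, labels as names.
#' @export
load_code_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  assert_that(all(c("comp_id", "label") %in% names(df)),
              sprintf("code table %s needs columns comp_id, label", path))
  stats::setNames(toupper(df$comp_id), df$label)
}

#' Default cofactor component codes shipped with the package
#' @return character vector of codes.
#' @export
default_cofactor_table <- function() {
  load_code_table(system.file("extdata", "cofactor_codes.tsv",
                              package = "sitevar", mustWork = TRUE))
}

#' Default crystallisation-artefact component codes shipped with the package
#' @return character vector of codes.
#' @export
default_artefact_table <- function() {
  load_code_table(system.file("extdata", "artefact_codes.tsv",
                              package = "sitevar", mustWork = TRUE))
}

#' Small-molecule definitions shipped with the package
#' @return named list of [small_molecule()] objects.
#' @export
default_molecules <- function() {
  load_molecules(system.file("extdata", "molecules.json",
                             package = "sitevar", mustWork = TRUE))
}
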