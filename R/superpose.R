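#' Superposition parameters
#'
#' @param c_param Gaussian weighting parameter c in Angstrom^2: per-atom
#'   weights are `exp(-d^2 / c)`. Smaller c locks the fit onto the invariant
#'   core more aggressively; `Inf` gives the classical uniform Kabsch fit.
#' @param tol convergence tolerance on the change in weighted RMSD (Angstrom).
#' @param max_iter maximum number of reweighting iterations.
#' @param table functional-triad table (see [triad_table()]).
#' @param trace record the per-iteration weighted objective (before and after
#'   each refit) in the result.
#' @return list of parameters.
#' @export
superposition_params <- function(c_param = 2.0, tol = 1e-5, max_iter = 50L,
                                 table = triad_table(), trace = FALSE) {
  assert_that(c_param > 0, "c_param must be positive")
  list(c_param = c_param, tol = tol, max_iter = as.integer(max_iter),
       table = table, trace = trace)
}

## Assemble stacked coordinate matrices and global exchangeability classes
## from a pair_residues() result. Gap slots are dropped.
assemble_pairing <- function(pairs) {
  keep <- Filter(function(p) p$kind != "gap", pairs)
  if (!length(keep)) {
    stop("no non-gap residue pairs to superpose", call. = FALSE)
  }
  A <- do.call(rbind, lapply(keep, `[[`, "xyz_a"))
  B <- do.call(rbind, lapply(keep, `[[`, "xyz_b"))
  slots <- rep(vapply(keep, `[[`, integer(1), "slot"),
               each = 3L)
  classes <- list()
  offset <- 0L
  for (p in keep) {
    for (g in p$symmetry_classes) {
      if (length(g) >= 2) classes <- c(classes, list(offset + g))
    }
    offset <- offset + 3L
  }
  atoms_a <- unlist(lapply(keep, `[[`, "atoms_a"))
  atoms_b <- unlist(lapply(keep, `[[`, "atoms_b"))
  list(A = A, B = B, slots = slots, classes = classes,
       atoms_a = atoms_a, atoms_b = atoms_b)
}

## Crude unweighted Kabsch fit for correspondence resolution: uses the
## name-unambiguous atoms when at least three exist, otherwise all atoms in
## file order (initialisation only).
crude_fit <- function(A, B, classes) {
  ambiguous <- unique(unlist(classes))
  unamb <- setdiff(seq_len(nrow(A)), ambiguous)
  idx <- if (length(unamb) >= 3) unamb else seq_len(nrow(A))
  Ai <- A[idx, , drop = FALSE]
  n <- nrow(Ai)
  Ac <- Ai - rep(colMeans(Ai), each = n)
  ## collinear point set: second eigenvalue of the 3 x 3 scatter vanishes
  ev <- eigen(crossprod(Ac), symmetric = TRUE, only.values = TRUE)$values
  degenerate <- ev[2] < 1e-16
  list(fit = wkabsch_kernel(Ai, B[idx, , drop = FALSE], c_param = Inf,
                            max_iter = 1L),
       degenerate = degenerate)
}

#' Resolve the atom correspondence between two paired sites
#'
#' Name-unambiguous atoms map directly; within each exchangeability class
#' (flipped His rings, swapped carboxylate oxygens, pseudo-mutated triads of
#' non-equivalent residues), the Kuhn-Munkres (Hungarian) algorithm finds the
#' minimum-total-distance bijection of the class after a crude unweighted
#' Kabsch superposition. Degenerate (collinear) geometry falls back to
#' name-order mapping with a warning.
#'
#' @param pairs result of [pair_residues()].
#' @return integer vector `m`: atom `i` of site A corresponds to atom `m[i]`
#'   of site B (indices over the stacked non-gap triad atoms); attributes
#'   `"atoms_a"`/`"atoms_b"` give the matched atom names.
#' @export
resolve_correspondence <- function(pairs) {
  asm <- assemble_pairing(pairs)
  mapping <- resolve_mapping(asm$A, asm$B, asm$classes)
  structure(mapping, atoms_a = asm$atoms_a, atoms_b = asm$atoms_b[mapping])
}

## internal: mapping on plain matrices
resolve_mapping <- function(A, B, classes) {
  mapping <- seq_len(nrow(A))
  if (!length(classes)) return(mapping)
  cf <- crude_fit(A, B, classes)
  if (cf$degenerate) {
    warning("degenerate (collinear) geometry in crude fit; falling back to name-order atom mapping",
            call. = FALSE)
    return(mapping)
  }
  At <- apply_transform(A, cf$fit$rotation, cf$fit$translation)
  for (cl in classes) {
    X <- At[cl, , drop = FALSE]
    Y <- B[cl, , drop = FALSE]
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    cost <- matrix(sqrt(pmax(0, d2)), nrow(d2), ncol(d2))
    perm <- solve_assignment(cost)
    mapping[cl] <- cl[perm]
  }
  mapping
}

## internal: full superposition on assembled matrices
superpose_core <- function(A, B, slots, classes, params) {
  n <- nrow(A)
  assert_that(n >= 3, "superposition needs at least 3 usable atom pairs")
  mapping <- resolve_mapping(A, B, classes)
  Bm <- B[mapping, , drop = FALSE]
  k <- wkabsch_kernel(A, Bm, c_param = params$c_param, tol = params$tol,
                      max_iter = params$max_iter, trace = params$trace)
  uslots <- unique(slots)
  per_res <- vapply(uslots, function(s) sqrt(mean(k$d2[slots == s])),
                    numeric(1))
  names(per_res) <- as.character(uslots)
  list(mapping = mapping, kernel = k, per_residue_rmsd = per_res,
       n_atoms = n)
}

#' Gaussian-weighted superposition of two homologous active sites
#'
#' Pairs the two sites residue-by-residue over functional atom triads
#' (handling conservative and non-equivalent mutations, and gaps), resolves
#' symmetric-atom ambiguity with the Hungarian algorithm after a crude Kabsch
#' fit, then iterates a Gaussian-weighted Kabsch fit: weights start uniform
#' and are updated to `exp(-d^2/c)` from the per-atom deviations, applying
#' positive bias to invariant regions of the site and negative bias to mobile
#' ones. The reported wRMSD is `sqrt(sum(w d^2) / sum(w))` under the final
#' weights; per-residue RMSDs are unweighted over each residue's mapped atoms
#' under the final transform.
#'
#' @param site_a,site_b positionally aligned [active_site()] objects; the
#'   fitted transform maps `site_a` onto `site_b`.
#' @param params see [superposition_params()].
#' @return object of class `superposition_result` with fields `rotation`,
#'   `translation`, `wrmsd`, `per_residue_rmsd` (named by slot),
#'   `max_residue_rmsd`, `n_atoms`, `correspondence` (data frame of matched
#'   atoms), `iterations`, `converged`, `weights` and (if traced)
#'   `objective_trace`.
#' @export
gaussian_weighted_superpose <- function(site_a, site_b,
                                        params = superposition_params()) {
  pairs <- pair_residues(site_a, site_b, params$table)
  asm <- assemble_pairing(pairs)
  core <- superpose_core(asm$A, asm$B, asm$slots, asm$classes, params)
  k <- core$kernel
  corr <- data.frame(slot = asm$slots,
                     atom_a = asm$atoms_a,
                     atom_b = asm$atoms_b[core$mapping],
                     stringsAsFactors = FALSE)
  structure(list(rotation = k$rotation, translation = k$translation,
                 wrmsd = k$wrmsd,
                 per_residue_rmsd = core$per_residue_rmsd,
                 max_residue_rmsd = max(core$per_residue_rmsd),
                 n_atoms = core$n_atoms, correspondence = corr,
                 iterations = k$iterations, converged = k$converged,
                 weights = k$weights, objective_trace = k$objective_trace,
                 site_a = site_a$site_id, site_b = site_b$site_id),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition %s -> %s> wRMSD %.3f A over %d atoms (%d iterations%s); max residue RMSD %.3f A\n",
              x$site_a, x$site_b, x$wrmsd, x$n_atoms, x$iterations,
              if (x$converged) ", converged" else ", NOT converged",
              x$max_residue_rmsd))
  invisible(x)
}

## ---- fast prepared path for all-vs-all scans ------------------------------

## Precompute stacked triad coordinates and symmetry classes for one site.
## Valid for pairing against another prepared site with identical residue
## names at every shared slot (the common conserved-family case).
prepare_site <- function(site, table = triad_table()) {
  n <- length(site$residues)
  tri <- vector("list", n)
  for (s in seq_len(n)) {
    r <- site$residues[[s]]
    if (!is.null(r)) tri[[s]] <- functional_triad(r, table)
  }
  ok <- which(!vapply(tri, is.null, logical(1)))
  xyz <- do.call(rbind, lapply(tri[ok], `[[`, "xyz"))
  names_by_slot <- vapply(seq_along(ok), function(i) {
    site$residues[[ok[i]]]$name
  }, character(1))
  list(site_id = site$site_id, slots = ok, xyz = xyz,
       names = names_by_slot,
       sym = lapply(tri[ok], `[[`, "symmetry_classes"))
}

## Superpose two prepared sites (matched residues only); falls back to the
## full object path on any name mismatch.
superpose_prepared <- function(pa, pb, params = superposition_params(),
                               per_residue = TRUE) {
  common <- intersect(pa$slots, pb$slots)
  ia <- match(common, pa$slots)
  ib <- match(common, pb$slots)
  if (!all(pa$names[ia] == pb$names[ib])) {
    stop("prepared superposition requires matched residue types", call. = FALSE)
  }
  rows_a <- as.vector(vapply(ia, function(i) (i - 1L) * 3L + 1:3, integer(3)))
  rows_b <- as.vector(vapply(ib, function(i) (i - 1L) * 3L + 1:3, integer(3)))
  A <- pa$xyz[rows_a, , drop = FALSE]
  B <- pb$xyz[rows_b, , drop = FALSE]
  classes <- list()
  for (i in seq_along(ia)) {
    for (g in pa$sym[[ia[i]]]) {
      if (length(g) >= 2) classes <- c(classes, list((i - 1L) * 3L + g))
    }
  }
  slots <- rep(common, each = 3L)
  core <- superpose_core(A, B, slots, classes, params)
  list(wrmsd = core$kernel$wrmsd,
       per_residue_rmsd = if (per_residue) core$per_residue_rmsd,
       max_residue_rmsd = max(core$per_residue_rmsd),
       converged = core$kernel$converged)
}
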