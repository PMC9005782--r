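## Maximum common connected substructure (MCS) between two small molecules,
## matching atoms by element and ignoring bond orders. Branch-and-bound
## backtracking: the mapping is grown one element-compatible atom pair at a
## time, each new pair connected to the mapped core through a bond present in
## BOTH molecules; at each step the search branches on including or excluding
## the next candidate pair, pruned by the attainable-size bound. Exact for
## the small-molecule sizes handled here; the engine is pluggable (any
## function (mol_a, mol_b) -> integer MCS size can replace it).

adjacency_list <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Size of the maximum common connected substructure
#'
#' @param mol_a,mol_b [small_molecule()] objects.
#' @return integer: number of atoms in the largest connected common
#'   substructure with element-identical matched atoms.
#' @export
mcs_size <- function(mol_a, mol_b) {
  ea <- mol_a$elements; eb <- mol_b$elements
  na_ <- length(ea); nb_ <- length(eb)
  if (na_ == 0 || nb_ == 0) return(0L)
  adj_a <- adjacency_list(mol_a)
  bond_b <- matrix(FALSE, nb_, nb_)
  if (nrow(mol_b$bonds)) {
    bond_b[mol_b$bonds[, 1:2, drop = FALSE]] <- TRUE
    bond_b[mol_b$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  best <- 0L

  ## candidate pairs extending a mapping: unmapped (u, w), equal element,
  ## u bonded in A to a mapped atom u0 with (w, map[u0]) bonded in B
  extensions <- function(map, used_b) {
    out <- list()
    mapped <- which(!is.na(map))
    if (!length(mapped)) {
      for (u in seq_len(na_)) {
        for (w in which(eb == ea[u])) {
          out[[length(out) + 1L]] <- c(u, w)
        }
      }
      return(out)
    }
    seen <- matrix(FALSE, na_, nb_)
    for (u0 in mapped) {
      for (u in adj_a[[u0]]) {
        if (!is.na(map[u])) next
        for (w in which(eb == ea[u] & !used_b & bond_b[, map[u0]])) {
          if (!seen[u, w]) {
            seen[u, w] <- TRUE
            out[[length(out) + 1L]] <- c(u, w)
          }
        }
      }
    }
    out
  }

  recurse <- function(map, used_b, excluded) {
    size <- sum(!is.na(map))
    if (size > best) best <<- size
    cand <- Filter(function(p) !excluded[p[1], p[2]],
                   extensions(map, used_b))
    if (!length(cand)) return(invisible())
    ## bound: even mapping every remaining candidate atom cannot beat best
    if (size + min(na_ - size, nb_ - size) <= best) return(invisible())
    p <- cand[[1]]
    map2 <- map; map2[p[1]] <- p[2]
    used2 <- used_b; used2[p[2]] <- TRUE
    recurse(map2, used2, excluded)
    excluded2 <- excluded; excluded2[p[1], p[2]] <- TRUE
    recurse(map, used_b, excluded2)
  }

  recurse(rep(NA_integer_, na_), rep(FALSE, nb_),
          matrix(FALSE, na_, nb_))
  as.integer(best)
}

#' Chemical similarity between two small molecules
#'
#' Atom-overlap similarity in `[0, 1]`: the proportion of atoms residing in
#' identical topology, computed from the maximum common connected
#' substructure (heavy atoms only, elements must match, bond orders ignored):
#' `m / (n_a + n_b - m)` where `m` is the MCS atom count. Undefined (returns
#' `NA`) for single-atom components; polymers are handled upstream and never
#' reach this function.
#'
#' @param mol_a,mol_b [small_molecule()] objects.
#' @param engine MCS engine, a function `(mol_a, mol_b) -> integer`;
#'   defaults to the exact in-package search.
#' @return similarity in `[0, 1]`, or `NA_real_` if undefined.
#' @examples
#' eth <- small_molecule("ETH", c("C", "C"), c(1, 2, 1))
#' eoh <- small_molecule("EOH", c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' parity_similarity(eth, eoh) # 2 / (2 + 3 - 2) = 0.667
#' @export
parity_similarity <- function(mol_a, mol_b, engine = mcs_size) {
  na_ <- length(mol_a$elements); nb_ <- length(mol_b$elements)
  if (na_ < 2 || nb_ < 2) return(NA_real_)
  if (!any(mol_a$elements %in% mol_b$elements)) return(0)
  m <- engine(mol_a, mol_b)
  m / (na_ + nb_ - m)
}
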