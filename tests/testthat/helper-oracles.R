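## Independent oracles and fixture builders used across the test files.

## all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

## exhaustive-permutation assignment oracle
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  pp <- all_permutations(n)
  costs <- apply(pp, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(cost = min(costs), assignment = pp[which.min(costs), ])
}

## exhaustive MCS oracle: enumerate every atom subset of the smaller
## molecule, every injective element-preserving map into the other, keep the
## common-edge subgraph and check its connectivity. Independent of the
## package's branch-and-bound search.
brute_force_mcs <- function(mol_a, mol_b) {
  if (length(mol_a$elements) > length(mol_b$elements)) {
    tmp <- mol_a; mol_a <- mol_b; mol_b <- tmp
  }
  na_ <- length(mol_a$elements); nb_ <- length(mol_b$elements)
  ea <- mol_a$elements; eb <- mol_b$elements
  bond_a <- matrix(FALSE, na_, na_)
  if (nrow(mol_a$bonds)) {
    bond_a[mol_a$bonds[, 1:2, drop = FALSE]] <- TRUE
    bond_a[mol_a$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  bond_b <- matrix(FALSE, nb_, nb_)
  if (nrow(mol_b$bonds)) {
    bond_b[mol_b$bonds[, 1:2, drop = FALSE]] <- TRUE
    bond_b[mol_b$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  connected <- function(nodes, adj) {
    if (length(nodes) <= 1) return(TRUE)
    seen <- nodes[1]
    repeat {
      grow <- nodes[vapply(nodes, function(v) {
        !(v %in% seen) && any(adj[v, seen])
      }, logical(1))]
      if (!length(grow)) break
      seen <- c(seen, grow)
    }
    length(seen) == length(nodes)
  }
  inject_maps <- function(subset) {
    ## all injective maps subset -> atoms of b with equal elements
    maps <- list(integer(0))
    for (u in subset) {
      cand <- which(eb == ea[u])
      maps <- unlist(lapply(maps, function(m) {
        lapply(setdiff(cand, m), function(w) c(m, w))
      }), recursive = FALSE)
      if (!length(maps)) return(list())
    }
    maps
  }
  best <- 0L
  for (mask in seq_len(2^na_ - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(na_) - 1)) > 0)
    if (length(subset) <= best) next
    for (m in inject_maps(subset)) {
      ## common edges: present in a (within subset) and in b (under the map)
      adj_common <- matrix(FALSE, na_, na_)
      for (i in seq_along(subset)) {
        for (j in seq_along(subset)) {
          u <- subset[i]; v <- subset[j]
          if (bond_a[u, v] && bond_b[m[i], m[j]]) {
            adj_common[u, v] <- TRUE
          }
        }
      }
      if (connected(subset, adj_common)) {
        best <- length(subset)
        break
      }
    }
  }
  best
}

## naive average-linkage (UPGMA) agglomeration oracle: returns merge heights
## and the flat assignment at a cut height
naive_upgma <- function(d, cut_height) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    if (length(clusters) == 1) break
  }
  ## assignment at cut: re-run, stopping at the first merge above cut_height
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    if (best[1] > cut_height) break
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  list(heights = heights, labels = labels)
}

## are two flat clusterings the same partition (up to label names)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

## build a simple planar-ring active site with deterministic per-residue
## orientations; `expand` moves every residue radially outward by that many
## Angstrom (all functional atoms deviate by exactly `expand` under the
## identity transform, which stays optimal by symmetry)
ring_site <- function(id = "s", types = c("ASP", "HIS", "ARG", "SER", "LYS",
                                          "GLU"),
                      radius = 5, expand = 0, seed = 99, resolution = 1.5,
                      accession = "P00001") {
  n <- length(types)
  angles <- 2 * pi * (seq_len(n) - 1) / n
  rots <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    sitevar:::random_rotation()
  }))
  residues <- lapply(seq_len(n), function(s) {
    center <- c((radius + expand) * cos(angles[s]),
                (radius + expand) * sin(angles[s]), 0)
    catalytic_residue(chain = "A", name = types[s], number = 10L * s,
                      function_location = "side_chain",
                      role = "proton donor", role_category = "reactant",
                      atoms = sitevar:::place_residue(types[s], center,
                                                      rots[[s]]))
  })
  active_site(site_id = id, structure_id = paste0(id, "_1"),
              residues = residues, resolution = resolution,
              experiment = "xray", sequence_accession = accession)
}

## displace one residue of a site by a vector
displace_residue <- function(site, slot, delta) {
  r <- site$residues[[slot]]
  r$atoms$x <- r$atoms$x + delta[1]
  r$atoms$y <- r$atoms$y + delta[2]
  r$atoms$z <- r$atoms$z + delta[3]
  site$residues[[slot]] <- r
  site
}

## add isotropic per-residue rigid noise to a site
jitter_site <- function(site, sigma, seed, id = site$site_id) {
  withr::with_seed(seed, {
    for (s in seq_along(site$residues)) {
      site <- displace_residue(site, s, rnorm(3, sd = sigma))
    }
  })
  site$site_id <- id
  site
}

## swap the coordinates of two named atoms within one residue (atom names
## keep their file order; only the positions are exchanged)
swap_atom_coords <- function(site, slot, name1, name2) {
  r <- site$residues[[slot]]
  i <- match(name1, r$atoms$name)
  j <- match(name2, r$atoms$name)
  tmp <- r$atoms[i, c("x", "y", "z")]
  r$atoms[i, c("x", "y", "z")] <- r$atoms[j, c("x", "y", "z")]
  r$atoms[j, c("x", "y", "z")] <- tmp
  site$residues[[slot]] <- r
  site
}

## single-atom "residues" at given centres: minimal sites for the sanity and
## centrality geometry tests (the atom is a CA so main-chain triads exist)
point_site <- function(id, centers, types = NULL, numbers = NULL) {
  n <- nrow(centers)
  if (is.null(types)) types <- rep("GLY", n)
  if (is.null(numbers)) numbers <- 10L * seq_len(n)
  residues <- lapply(seq_len(n), function(s) {
    catalytic_residue(chain = "A", name = types[s], number = numbers[s],
                      function_location = "main_chain",
                      atoms = atom_table(name = "CA", x = centers[s, 1],
                                         y = centers[s, 2],
                                         z = centers[s, 3]))
  })
  active_site(site_id = id, structure_id = paste0(id, "_1"),
              residues = residues)
}

## apply a rigid transform to every residue of a site
transform_site <- function(site, rotation, translation) {
  for (s in seq_along(site$residues)) {
    r <- site$residues[[s]]
    if (is.null(r)) next
    xyz <- sitevar:::apply_transform(as.matrix(r$atoms[, c("x", "y", "z")]),
                                     rotation, translation)
    r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
    site$residues[[s]] <- r
  }
  site
}
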