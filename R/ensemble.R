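## Family-level structural analyses: pairwise comparison tables, all-vs-all
## RMSD matrices, dataset clean-up filters, ligand-state grouping,
## conformer clustering, flexibility quadrants and residue-role enrichment.

## CA coordinates of the shared filled slots of two aligned sites
common_ca <- function(site_a, site_b) {
  idx <- intersect(filled_slots(site_a), filled_slots(site_b))
  ca <- function(r) {
    i <- match("CA", r$atoms$name)
    if (is.na(i)) NULL else as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  A <- lapply(site_a$residues[idx], ca)
  B <- lapply(site_b$residues[idx], ca)
  ok <- !vapply(A, is.null, logical(1)) & !vapply(B, is.null, logical(1))
  list(A = do.call(rbind, A[ok]), B = do.call(rbind, B[ok]))
}

#' Compare two homologous active sites
#'
#' Runs the Gaussian-weighted functional-atom superposition plus a plain
#' (uniform) Kabsch fit over the shared C-alpha atoms, and collects the pair
#' metadata used by the clean-up filters and grouping analyses.
#'
#' @param site_a,site_b positionally aligned [active_site()] objects.
#' @param params superposition parameters.
#' @return list with the `superposition` result, `ca_rmsd`, and a one-row
#'   `row` data frame (site ids, same_protein, conserved, wrmsd,
#'   max_residue_rmsd, ca_rmsd, resolutions, experiments, gap flag,
#'   intra-residue distance discrepancy).
#' @export
compare_sites <- function(site_a, site_b, params = superposition_params()) {
  sp <- gaussian_weighted_superpose(site_a, site_b, params)
  cc <- common_ca(site_a, site_b)
  ca_rmsd <- if (!is.null(cc$A) && nrow(cc$A) >= 3) {
    kabsch(cc$A, cc$B)$rmsd
  } else NA_real_
  shared <- intersect(filled_slots(site_a), filled_slots(site_b))
  conserved <- all(vapply(shared, function(s) {
    site_a$residues[[s]]$name == site_b$residues[[s]]$name
  }, logical(1)))
  has_gap <- length(shared) < length(site_a$residues)
  same_protein <- !is.na(site_a$sequence_accession) &&
    !is.na(site_b$sequence_accession) &&
    site_a$sequence_accession == site_b$sequence_accession
  row <- data.frame(
    site_a = site_a$site_id, site_b = site_b$site_id,
    same_protein = same_protein, conserved = conserved,
    wrmsd = sp$wrmsd, max_residue_rmsd = sp$max_residue_rmsd,
    ca_rmsd = ca_rmsd,
    resolution_a = site_a$resolution, resolution_b = site_b$resolution,
    experiment_a = site_a$experiment, experiment_b = site_b$experiment,
    has_gap = has_gap,
    intra_discrepancy = abs(mean_intra_distance(site_a) -
                              mean_intra_distance(site_b)),
    n_atoms = sp$n_atoms, stringsAsFactors = FALSE)
  list(superposition = sp, ca_rmsd = ca_rmsd, row = row)
}

ligand_state_of <- function(bound_a, bound_b) {
  ifelse(bound_a & bound_b, "bound_bound",
         ifelse(!bound_a & !bound_b, "free_free", "bound_free"))
}

#' All-vs-all pair comparison table for one family
#'
#' @param sites list of aligned [active_site()] objects.
#' @param family_id family identifier attached to every row.
#' @param bound optional logical vector (is each site ligand-bound?); adds a
#'   `ligand_state` column (free_free / bound_bound / bound_free).
#' @param ec_number optional EC number; its absence marks rows for the
#'   no-EC exclusion of the ligand-effect filter profile.
#' @param params superposition parameters.
#' @return list with `pairs` (one row per unordered site pair) and
#'   `residues` (per-residue RMSD records: slot, residue type, role,
#'   category, rmsd).
#' @export
family_pair_table <- function(sites, family_id = "FAM", bound = NULL,
                              ec_number = "0.0.0.0",
                              params = superposition_params()) {
  n <- length(sites)
  assert_that(n >= 2, "need at least two sites")
  pair_rows <- list()
  res_rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmp <- compare_sites(sites[[i]], sites[[j]], params)
      row <- cmp$row
      row$family_id <- family_id
      row$has_ec <- !is.null(ec_number) && !is.na(ec_number)
      if (!is.null(bound)) {
        row$ligand_state <- ligand_state_of(bound[i], bound[j])
      }
      pair_rows[[length(pair_rows) + 1L]] <- row
      pr <- cmp$superposition$per_residue_rmsd
      slots <- as.integer(names(pr))
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        family_id = family_id,
        site_a = sites[[i]]$site_id, site_b = sites[[j]]$site_id,
        slot = slots,
        residue_type = vapply(slots, function(s)
          sites[[i]]$residues[[s]]$name, character(1)),
        role = vapply(slots, function(s)
          sites[[i]]$residues[[s]]$role, character(1)),
        category = vapply(slots, function(s)
          sites[[i]]$residues[[s]]$role_category, character(1)),
        rmsd = unname(pr), stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, pair_rows),
       residues = do.call(rbind, res_rows))
}

#' All-vs-all RMSD matrix over a set of homologous sites
#'
#' `mode = "functional"` uses the Gaussian-weighted superposition over
#' functional atom triads; `mode = "ca"` a plain Kabsch fit over shared
#' C-alpha atoms. Pairs failing superposition give `NA` cells (logged via
#' warning). The result is symmetrised with a zero diagonal.
#'
#' @param sites list of aligned [active_site()] objects (>= 2).
#' @param mode `"functional"` or `"ca"`.
#' @param params superposition parameters.
#' @return symmetric numeric matrix (Angstrom) with site ids as dimnames.
#' @export
all_vs_all_matrix <- function(sites, mode = c("functional", "ca"),
                              params = superposition_params()) {
  mode <- match.arg(mode)
  n <- length(sites)
  assert_that(n >= 2, "need at least two sites")
  ids <- vapply(sites, `[[`, character(1), "site_id")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  prepared <- if (mode == "functional") {
    lapply(sites, prepare_site, table = params$table)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- tryCatch({
        if (mode == "functional") {
          pa <- prepared[[i]]; pb <- prepared[[j]]
          common <- intersect(pa$slots, pb$slots)
          if (length(common) &&
              all(pa$names[match(common, pa$slots)] ==
                    pb$names[match(common, pb$slots)])) {
            superpose_prepared(pa, pb, params, per_residue = FALSE)$wrmsd
          } else {
            gaussian_weighted_superpose(sites[[i]], sites[[j]],
                                        params)$wrmsd
          }
        } else {
          cc <- common_ca(sites[[i]], sites[[j]])
          if (is.null(cc$A) || nrow(cc$A) < 3) {
            stop("fewer than 3 shared C-alpha atoms")
          }
          kabsch(cc$A, cc$B)$rmsd
        }
      }, error = function(e) {
        warning(sprintf("pair (%s, %s) failed: %s", ids[i], ids[j],
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      m[i, j] <- m[j, i] <- val
    }
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

## append exclusion log rows
log_exclusions <- function(log, pairs, rule) {
  if (!nrow(pairs)) return(log)
  rbind(log, data.frame(site_a = pairs$site_a, site_b = pairs$site_b,
                        rule = rule, stringsAsFactors = FALSE))
}

#' Apply a dataset clean-up profile to a pair-comparison table
#'
#' `"seq_struct"` (sequence vs structure analyses): resolution at most 2.0
#' Angstrom on both sides, no NMR structures, RMSD at most 10 Angstrom, and
#' the number of comparisons per family capped at 30 by seeded random
#' sampling. `"ligand_effect"`: the same resolution/NMR rules, plus: no
#' missing EC number, no gapped sites, mean intra-residue distance
#' discrepancy at most 5 Angstrom, wRMSD at most 10, maximum single-residue
#' RMSD at most 20, and exclusion of suspect fits with wRMSD above 1.5 where
#' the maximum residue RMSD exceeds 3 times the wRMSD.
#'
#' @param pairs data frame from [family_pair_table()]`$pairs`.
#' @param profile `"seq_struct"` or `"ligand_effect"`.
#' @param seed RNG seed for the per-family sampling cap.
#' @param cap maximum comparisons per family under `"seq_struct"`.
#' @return the retained rows; attribute `"exclusions"` is a data frame
#'   (site_a, site_b, rule) logging every excluded pair with its rule tag.
#' @export
apply_pair_filters <- function(pairs, profile = c("seq_struct",
                                                  "ligand_effect"),
                               seed = 0, cap = 30) {
  profile <- match.arg(profile)
  log <- data.frame(site_a = character(0), site_b = character(0),
                    rule = character(0), stringsAsFactors = FALSE)
  drop_rule <- function(df, bad, rule) {
    log <<- log_exclusions(log, df[bad, , drop = FALSE], rule)
    df[!bad, , drop = FALSE]
  }
  p <- pairs
  bad_res <- with(p, is.na(resolution_a) | is.na(resolution_b) |
                    resolution_a > 2 | resolution_b > 2)
  p <- drop_rule(p, bad_res, "resolution_gt_2")
  p <- drop_rule(p, p$experiment_a == "nmr" | p$experiment_b == "nmr", "nmr")
  if (profile == "seq_struct") {
    p <- drop_rule(p, !is.na(p$ca_rmsd) & p$ca_rmsd > 10 | p$wrmsd > 10,
                   "rmsd_gt_10")
    keep <- with_seed(seed, {
      unlist(lapply(split(seq_len(nrow(p)), p$family_id), function(rows) {
        if (length(rows) <= cap) rows else sort(sample(rows, cap))
      }))
    })
    p_keep <- p[sort(keep), , drop = FALSE]
    dropped <- p[setdiff(seq_len(nrow(p)), keep), , drop = FALSE]
    log <- log_exclusions(log, dropped, "family_cap_sample")
    p <- p_keep
  } else {
    p <- drop_rule(p, !p$has_ec, "no_ec")
    p <- drop_rule(p, p$has_gap, "gap_in_site")
    p <- drop_rule(p, !is.na(p$intra_discrepancy) & p$intra_discrepancy > 5,
                   "intra_dist_discrepancy_gt_5")
    p <- drop_rule(p, p$wrmsd > 10, "wrmsd_gt_10")
    p <- drop_rule(p, p$max_residue_rmsd > 20, "max_res_rmsd_gt_20")
    p <- drop_rule(p, p$wrmsd > 1.5 & p$max_residue_rmsd > 3 * p$wrmsd,
                   "outlier_ratio_3x")
  }
  structure(p, exclusions = log)
}

#' Group pairs by protein identity, conservation and ligand state
#'
#' The twelve-bucket grouping: same vs different protein, conserved vs
#' mutated catalytic residues, and free/free vs bound/bound vs bound/free
#' ligand states, with the mean wRMSD computed per family within each bucket.
#'
#' @param pairs pair table with `same_protein`, `conserved`, `ligand_state`,
#'   `family_id` and `wrmsd` columns.
#' @return data frame: one row per non-empty (bucket, family), with
#'   `mean_wrmsd` and `n_pairs`.
#' @export
group_pairs_by_ligand_state <- function(pairs) {
  assert_that(!is.null(pairs$ligand_state),
              "pairs need a ligand_state column (see family_pair_table(bound=))")
  key <- interaction(pairs$same_protein, pairs$conserved, pairs$ligand_state,
                     pairs$family_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(pairs)), key), function(r) {
    data.frame(same_protein = pairs$same_protein[r[1]],
               conserved = pairs$conserved[r[1]],
               ligand_state = pairs$ligand_state[r[1]],
               family_id = pairs$family_id[r[1]],
               mean_wrmsd = mean(pairs$wrmsd[r]),
               n_pairs = length(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$same_protein, out$conserved, out$ligand_state,
            out$family_id), , drop = FALSE]
}

#' Cluster homologous sites from an all-vs-all RMSD matrix
#'
#' Hierarchical (average linkage by default) clustering of the dissimilarity
#' matrix; the dendrogram is pruned at a height equal to `prune_factor`
#' times the maximum merge height. `NA` cells are imputed with the matrix
#' maximum (logged via warning).
#'
#' @param m symmetric RMSD matrix with site ids as dimnames.
#' @param prune_factor fraction of the maximum merge height at which the
#'   dendrogram is cut (default 0.4).
#' @param method linkage method for [stats::hclust()].
#' @return list with `labels` (named integer cluster assignment), `tree`
#'   (the `hclust` object) and `cut_height`.
#' @export
cluster_sites <- function(m, prune_factor = 0.4, method = "average") {
  if (anyNA(m)) {
    warning(sprintf("%d NA cell(s) imputed with the matrix maximum",
                    sum(is.na(m)) / 2), call. = FALSE)
    m[is.na(m)] <- max(m, na.rm = TRUE)
  }
  hc <- stats::hclust(stats::as.dist(m), method = method)
  cut_height <- prune_factor * max(hc$height)
  ## epsilon absorbs numerically-zero merge heights (identical sites)
  labels <- stats::cutree(hc, h = cut_height + 1e-9)
  list(labels = labels, tree = hc, cut_height = cut_height)
}

#' Flexibility quadrant of an active-site pair
#'
#' Classifies a pair by comparing its main-chain (C-alpha) and functional
#' (side-chain) RMSD to a threshold taken as the limit of experimental error
#' (0.5 Angstrom): rigid below the threshold, flexible at or above it.
#'
#' @param ca_rmsd main-chain RMSD values (Angstrom).
#' @param functional_rmsd functional-atom RMSD values.
#' @param threshold rigid/flexible boundary (default 0.5; flexible is
#'   inclusive: RMSD >= threshold).
#' @return factor with levels rigid_both, flexible_both, side_chain_only,
#'   main_chain_only.
#' @export
flexibility_quadrant <- function(ca_rmsd, functional_rmsd, threshold = 0.5) {
  assert_that(all(ca_rmsd >= 0, na.rm = TRUE) &&
                all(functional_rmsd >= 0, na.rm = TRUE),
              "RMSD values must be non-negative")
  main_flex <- ca_rmsd >= threshold
  side_flex <- functional_rmsd >= threshold
  out <- ifelse(main_flex & side_flex, "flexible_both",
                ifelse(!main_flex & !side_flex, "rigid_both",
                       ifelse(side_flex, "side_chain_only",
                              "main_chain_only")))
  factor(out, levels = c("rigid_both", "flexible_both", "side_chain_only",
                         "main_chain_only"))
}

#' Residue-type/role/category enrichment odds ratios
#'
#' Splits per-residue RMSD records into rigid (< threshold) and flexible
#' (>= threshold) partitions after capping the number of superposition pairs
#' sampled per family, computes the within-partition frequencies of each
#' residue type, functional role and role category, and reports the
#' flexible-over-rigid odds ratio (> 1: the group tends to be flexible).
#' Groups occupying less than `min_share` of the sampled records are
#' suppressed; groups absent from the rigid partition are reported with an
#' infinite odds ratio marker.
#'
#' @param records data frame with columns family_id, site_a, site_b,
#'   residue_type, role, category, rmsd (see [family_pair_table()]).
#' @param sample_per_family cap on sampled superposition pairs per family.
#' @param seed RNG seed for the sampling.
#' @param threshold rigid/flexible boundary (Angstrom).
#' @param min_share minimum combined share of the sampled dataset a group
#'   must occupy to be reported (default 0.02).
#' @return data frame: grouping (residue_type / role / category), level,
#'   freq_flexible, freq_rigid, odds_ratio, n_flexible, n_rigid.
#' @export
enrichment_odds_ratios <- function(records, sample_per_family = 50,
                                   seed = 0, threshold = 0.5,
                                   min_share = 0.02) {
  pair_key <- paste(records$family_id, records$site_a, records$site_b,
                    sep = "|")
  sampled_keys <- with_seed(seed, {
    unlist(lapply(split(unique(pair_key), sub("\\|.*", "", unique(pair_key))),
                  function(keys) {
      if (length(keys) <= sample_per_family) keys
      else sample(keys, sample_per_family)
    }))
  })
  rec <- records[pair_key %in% sampled_keys, , drop = FALSE]
  flex <- rec$rmsd >= threshold
  n_flex <- sum(flex)
  n_rigid <- sum(!flex)
  assert_that(n_flex > 0 && n_rigid > 0,
              "need records in both the rigid and the flexible partition")
  out <- list()
  for (grouping in c("residue_type", "role", "category")) {
    for (lev in sort(unique(rec[[grouping]]))) {
      in_g <- rec[[grouping]] == lev
      share <- sum(in_g) / nrow(rec)
      if (share < min_share) next
      ff <- sum(in_g & flex) / n_flex
      fr <- sum(in_g & !flex) / n_rigid
      out[[length(out) + 1L]] <- data.frame(
        grouping = grouping, level = lev, freq_flexible = ff,
        freq_rigid = fr,
        odds_ratio = if (fr == 0) Inf else ff / fr,
        n_flexible = sum(in_g & flex), n_rigid = sum(in_g & !flex),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
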