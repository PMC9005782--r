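## hand-built pair table rows for the filter tests
pair_row <- function(wrmsd, max_res = wrmsd, ca = wrmsd, res_a = 1.5,
                     res_b = 1.5, exp_a = "xray", exp_b = "xray",
                     has_ec = TRUE, has_gap = FALSE, intra = 0,
                     family = "F1", id = "x", same_protein = TRUE,
                     conserved = TRUE, ligand_state = "free_free") {
  data.frame(site_a = paste0(id, "_a"), site_b = paste0(id, "_b"),
             same_protein = same_protein, conserved = conserved,
             wrmsd = wrmsd, max_residue_rmsd = max_res, ca_rmsd = ca,
             resolution_a = res_a, resolution_b = res_b,
             experiment_a = exp_a, experiment_b = exp_b, has_gap = has_gap,
             intra_discrepancy = intra, n_atoms = 18L, family_id = family,
             has_ec = has_ec, ligand_state = ligand_state,
             stringsAsFactors = FALSE)
}

test_that("all-vs-all matrices recover planted radial expansions", {
  a <- ring_site("a")
  b <- ring_site("b", expand = 0.1)
  c_ <- ring_site("c", expand = 2.0)
  ## every functional atom of an expanded ring deviates by exactly the
  ## expansion magnitude, and the identity transform is optimal by symmetry;
  ## check the plant under uniform weights, where RMSD = expansion
  uni <- superposition_params(c_param = Inf)
  m <- all_vs_all_matrix(list(a, b, c_), params = uni)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0), ignore_attr = TRUE)
  expect_true(isSymmetric(m))
  expect_equal(m["a", "b"], 0.1, tolerance = 0.05)
  expect_equal(m["a", "c"], 2.0, tolerance = 0.05)
  expect_equal(m["b", "c"], 1.9, tolerance = 0.05)
  ## the Gaussian-weighted distance is compressed for large coherent
  ## displacements but preserves the ordering
  mw <- all_vs_all_matrix(list(a, b, c_))
  expect_equal(mw["a", "b"], 0.1, tolerance = 0.05)
  expect_true(mw["a", "c"] > 5 * mw["a", "b"])
  expect_lte(mw["a", "c"], m["a", "c"] + 1e-9)
  ## identical sites: zero matrix
  m0 <- all_vs_all_matrix(list(a, transform_site(
    a, withr::with_seed(1, sitevar:::random_rotation()), c(5, 5, 5))))
  expect_true(all(m0 < 1e-9))
  ## C-alpha mode is plain unweighted Kabsch over CA atoms
  mca <- all_vs_all_matrix(list(a, c_), mode = "ca")
  expect_equal(mca["a", "c"], 2.0, tolerance = 0.05)
})

test_that("clean-up filters fire on the stated boundaries and are idempotent", {
  pairs <- rbind(
    pair_row(1.6, max_res = 5.0, id = "excl"),  # 5.0 > 3 * 1.6
    pair_row(1.6, max_res = 4.0, id = "keep"),  # 4.0 < 4.8
    pair_row(0.4, res_a = 2.5, id = "badres"),
    pair_row(0.4, exp_b = "nmr", id = "nmr"),
    pair_row(11, max_res = 11, id = "bigw"),
    pair_row(2.0, max_res = 21, id = "bigres"),
    pair_row(0.4, has_ec = FALSE, id = "noec"),
    pair_row(0.4, has_gap = TRUE, id = "gap"),
    pair_row(0.4, intra = 5.5, id = "intra"))
  out <- apply_pair_filters(pairs, "ligand_effect")
  expect_equal(out$site_a, "keep_a")
  log <- attr(out, "exclusions")
  rule_of <- function(id) log$rule[log$site_a == paste0(id, "_a")]
  expect_equal(rule_of("excl"), "outlier_ratio_3x")
  expect_equal(rule_of("badres"), "resolution_gt_2")
  expect_equal(rule_of("nmr"), "nmr")
  expect_equal(rule_of("bigw"), "wrmsd_gt_10")
  expect_equal(rule_of("bigres"), "max_res_rmsd_gt_20")
  expect_equal(rule_of("noec"), "no_ec")
  expect_equal(rule_of("gap"), "gap_in_site")
  expect_equal(rule_of("intra"), "intra_dist_discrepancy_gt_5")
  ## idempotence (same retained rows; the second pass excludes nothing)
  twice <- apply_pair_filters(out, "ligand_effect")
  expect_equal(twice$site_a, out$site_a)
  expect_equal(nrow(attr(twice, "exclusions")), 0)
})

test_that("family sampling cap retains exactly 30 pairs, reproducibly", {
  pairs <- do.call(rbind, lapply(1:100, function(i) {
    pair_row(0.4, id = paste0("p", i))
  }))
  out1 <- apply_pair_filters(pairs, "seq_struct", seed = 42)
  out2 <- apply_pair_filters(pairs, "seq_struct", seed = 42)
  expect_equal(nrow(out1), 30)
  expect_equal(out1$site_a, out2$site_a)
  out3 <- apply_pair_filters(pairs, "seq_struct", seed = 43)
  expect_false(identical(out1$site_a, out3$site_a))
  ## below the cap the set is untouched (and the filter is idempotent)
  again <- apply_pair_filters(out1, "seq_struct", seed = 42)
  expect_equal(again$site_a, out1$site_a)
})

test_that("ligand-state buckets follow pair combinatorics", {
  sites <- lapply(1:5, function(i) {
    jitter_site(ring_site(paste0("s", i), seed = 99), 0.05, seed = i,
                id = paste0("s", i))
  })
  bound <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  tbl <- family_pair_table(sites, family_id = "FAM1", bound = bound)
  counts <- table(tbl$pairs$ligand_state)
  expect_equal(as.integer(counts[c("free_free", "bound_bound",
                                   "bound_free")]), c(3L, 1L, 6L))
  grouped <- group_pairs_by_ligand_state(tbl$pairs)
  expect_equal(grouped$n_pairs[match(c("bound_bound", "bound_free",
                                       "free_free"),
                                     grouped$ligand_state)],
               c(1L, 6L, 3L))
  ## all-mutated pairs leave the conserved buckets empty
  mut <- tbl$pairs
  mut$conserved <- FALSE
  expect_false(any(group_pairs_by_ligand_state(mut)$conserved))
})

test_that("ligand binding stabilises sites in the planted simulation", {
  fam <- generate_site_ensemble(ensemble_spec(
    "flexible", n_sites = 14, bound_fraction = 0.5, sigma_bound = 0.1,
    sigma_free = 0.5, seed = 20))
  truth <- attr(fam, "truth")
  expect_true(any(truth$bound) && any(!truth$bound))
  tbl <- family_pair_table(fam$homologs, family_id = fam$family_id,
                           bound = truth$bound)
  g <- group_pairs_by_ligand_state(tbl$pairs)
  mw <- function(state) g$mean_wrmsd[g$ligand_state == state]
  expect_lt(mw("bound_bound"), mw("free_free"))
  expect_lt(mw("bound_bound"), mw("bound_free"))
})

test_that("site clustering prunes at 0.4 of the maximum merge height", {
  ## two tight conformer groups 2.5 A apart
  g1 <- lapply(1:3, function(i) jitter_site(ring_site(paste0("a", i),
                                                      seed = 99),
                                            0.05, seed = i,
                                            id = paste0("a", i)))
  g2 <- lapply(1:3, function(i) {
    s <- ring_site(paste0("b", i), expand = 2.5, seed = 99)
    jitter_site(s, 0.05, seed = 10 + i, id = paste0("b", i))
  })
  m <- all_vs_all_matrix(c(g1, g2))
  cl <- cluster_sites(m)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_equal(cl$cut_height, 0.4 * max(cl$tree$height))
  ## all-identical sites collapse into one cluster
  same <- all_vs_all_matrix(list(ring_site("x"), ring_site("y"),
                                 ring_site("z")))
  expect_equal(length(unique(cluster_sites(same)$labels)), 1)
  ## NA cells are imputed with the matrix maximum
  m_na <- m
  m_na[1, 4] <- m_na[4, 1] <- NA
  expect_warning(cl2 <- cluster_sites(m_na), "imputed")
  expect_equal(length(unique(cl2$labels)), 2)
})

test_that("average-linkage clustering agrees with a naive UPGMA oracle", {
  withr::with_seed(7, {
    for (k in 1:5) {
      n <- 6
      pts <- matrix(rnorm(2 * n, sd = 2), n)
      d <- as.matrix(dist(pts))
      dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
      cl <- cluster_sites(d)
      oracle <- naive_upgma(d, cl$cut_height)
      expect_equal(sort(cl$tree$height), sort(oracle$heights),
                   tolerance = 1e-9)
      expect_true(same_partition(unname(cl$labels), oracle$labels))
    }
  })
})

test_that("flexibility quadrants split at the 0.5 A boundary", {
  expect_equal(as.character(flexibility_quadrant(0.2, 0.3)), "rigid_both")
  expect_equal(as.character(flexibility_quadrant(0.2, 0.9)),
               "side_chain_only")
  expect_equal(as.character(flexibility_quadrant(0.9, 0.2)),
               "main_chain_only")
  ## the boundary itself is flexible (>= threshold)
  expect_equal(as.character(flexibility_quadrant(0.5, 0.5)),
               "flexible_both")
  q <- flexibility_quadrant(runif(200), runif(200))
  expect_equal(sum(table(q)) / length(q), 1)
  expect_error(flexibility_quadrant(-0.1, 0.2), "non-negative")
})

test_that("enrichment odds ratios match hand arithmetic", {
  ## His: 10 of 100 flexible records, 30 of 100 rigid -> OR 1/3
  mk <- function(type, rmsd, n, offset = 0) {
    data.frame(family_id = "F1", site_a = paste0("a", offset + seq_len(n)),
               site_b = "b", slot = 1L, residue_type = type, role = "r",
               category = "reactant", rmsd = rmsd, stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("HIS", 0.9, 10), mk("ASP", 0.9, 90, 10),
               mk("HIS", 0.1, 30, 100), mk("ASP", 0.1, 70, 130))
  out <- enrichment_odds_ratios(rec, sample_per_family = 1000)
  his <- out[out$grouping == "residue_type" & out$level == "HIS", ]
  expect_equal(his$freq_flexible, 0.1)
  expect_equal(his$freq_rigid, 0.3)
  expect_equal(his$odds_ratio, 1 / 3, tolerance = 1e-12)
  ## a type present only below the threshold gets the infinite marker
  rec2 <- rbind(rec, mk("ZZZ", 0.9, 10, 300))
  out2 <- enrichment_odds_ratios(rec2, sample_per_family = 1000)
  expect_equal(out2$odds_ratio[out2$level == "ZZZ"], Inf)
  ## rare groups below the 2% floor are suppressed
  rec3 <- rbind(rec, mk("QQQ", 0.9, 2, 400))
  out3 <- enrichment_odds_ratios(rec3, sample_per_family = 1000)
  expect_false("QQQ" %in% out3$level)
})

test_that("planted role-dependent noise is recovered as enrichment", {
  ## reactant slots get 0.1 A noise, spectator slots 1.0 A
  fams <- lapply(1:3, function(k) {
    roles <- sitevar:::.ensemble_roles$category[1:6]
    sig <- ifelse(roles == "spectator", 1.0, 0.1)
    generate_site_ensemble(ensemble_spec("rigid", n_sites = 10,
                                         sigma = sig, seed = 30 + k))
  })
  recs <- do.call(rbind, lapply(seq_along(fams), function(k) {
    tbl <- family_pair_table(fams[[k]]$homologs,
                             family_id = paste0("F", k))
    tbl$residues
  }))
  out <- enrichment_odds_ratios(recs, sample_per_family = 50, seed = 1)
  or <- function(lev) out$odds_ratio[out$grouping == "category" &
                                       out$level == lev]
  expect_gt(or("spectator"), 1)
  expect_lt(or("reactant"), 1)
})

test_that("paradigm calls require enough sites and degrade gracefully", {
  call_ <- classify_paradigm(runif(10), n_sites = 5)
  expect_equal(call_$label, "unclassified")
  expect_equal(classify_paradigm(numeric(0), n_sites = 100)$label,
               "unclassified")
  ## a clean planted mixture is open/closed even without the generator
  x <- withr::with_seed(8, c(rnorm(300, 0.3, 0.05), rnorm(300, 2.2, 0.1)))
  expect_equal(classify_paradigm(x, n_sites = 60)$label, "open_closed")
})
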