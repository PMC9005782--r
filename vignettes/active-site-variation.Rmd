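---
title: "Quantifying conformational variation in enzyme active sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational variation in enzyme active sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Catalytic residues are the functional core of an enzyme. Across the many
crystal structures of one homologous family, the active site is captured in
different conformational states: side chains flip, loops carrying catalytic
residues move, domains open and close around the substrate. `sitevar`
reconstructs active sites from multi-chain structures, superposes homologous
sites over the atoms that actually perform the chemistry, and summarises how
a family behaves: is its site inherently rigid, inherently flexible, a
two-state (open/closed) switch, or extensively variable?

The pipeline has four stages, each usable on its own:

1. **Site reconstruction** (`build_active_sites()`): group the annotated
   catalytic residues of an assembly into one site per enzyme copy, check
   the geometry against the curated reference, drop redundant copies.
2. **Ligand annotation** (`annotate_ligands()`): find components adjacent to
   (3 Å) and peripheral to (30 Å) the site and classify them as
   substrate-like, cofactor, crystallisation artefact, or uncertain.
3. **Superposition** (`gaussian_weighted_superpose()`): a symmetry-aware,
   Gaussian-weighted rigid fit over functional atom triads, reporting a
   global weighted RMSD (wRMSD) and unweighted per-residue RMSDs.
4. **Family analysis** (`all_vs_all_matrix()`, `classify_paradigm()`,
   `cluster_sites()`, `flexibility_quadrant()`,
   `enrichment_odds_ratios()`): matrices, filters, conformer clusters,
   paradigm calls and flexibility enrichment.

## Functional atom triads and mutation handling

Each catalytic residue contributes exactly three atoms from the moiety that
performs its function (`triad_table()`): Arg is anchored by its guanidino
endpoint atoms (CZ, NH1, NH2), Asp by its carboxylate plane (CG, OD1, OD2),
and so on. Residues functioning through the main chain, or carrying
post-translational modifications, use (N, CA, C). Fitting on triads lets the
non-functional part of the residue vary without biasing the alignment.

When the two sites differ in sequence, `pair_residues()` distinguishes:

* **conservative mismatches** within the sets Asp–Glu, Asn–Gln,
  Ser–Thr–Tyr, Val–Leu–Ile: the chemically analogous triad atoms are paired
  positionally (triads are listed inner-to-outer for this reason);
* **non-equivalent mismatches**: all three atoms are pseudo-mutated to a
  common wildcard and treated as mutually exchangeable;
* **gaps** (a residue missing on either side, or a triad atom absent from
  the coordinates): the slot is excluded from the fit entirely.

Some functional groups are ambiguous in electron density: the terminal
oxygens of Asp/Glu, the His ring atoms (treated as one exchange class to
allow ring flips), the symmetric methyls of Val/Leu, the CE atoms of Phe.
`resolve_correspondence()` fixes the mapping of every exchange class with
the Kuhn–Munkres (Hungarian) algorithm on pairwise Euclidean distances after
a crude unweighted Kabsch fit on the name-unambiguous atoms. On degenerate
(collinear) geometry the resolver falls back to name-order mapping with a
warning rather than trusting an ill-conditioned crude fit.

## The Gaussian-weighted fit

A plain least-squares superposition spreads the deviation of one mobile
residue over the whole site. The weighted fit iterates:

1. weighted Kabsch fit with current weights (starting uniform);
2. per-atom deviations $d_i$ under the fitted transform;
3. $w_i \leftarrow \exp(-d_i^2 / c)$;

until the weighted RMSD
$\mathrm{wRMSD} = \sqrt{\sum_i w_i d_i^2 / \sum_i w_i}$ changes by less than
`tol` between iterations. Invariant regions are thereby up-weighted and
mobile regions down-weighted, so the fit locks onto the rigid core; the
displaced residues then show their true displacement in the **unweighted**
per-residue RMSDs computed under the final transform.

Numerical choices (all in `superposition_params()`):

* `c_param = 2.0` Å²: the Gaussian width. `Inf` recovers the classical
  Kabsch fit exactly (a tested invariant). Weights are floored at 1e-12 so a
  pathological all-large-deviation step cannot zero out the fit.
* `tol = 1e-5` Å on the change in wRMSD, `max_iter = 50`. Typical pairs
  converge in 4–20 iterations; non-convergence returns the best iterate
  flagged `converged = FALSE`.
* Reflections are corrected inside the Kabsch solver by flipping the sign of
  the smallest singular component, so mirror-image inputs always yield a
  proper rotation (det = +1).
* One caveat follows from the weighting itself: for large *coherent*
  displacements (half the site moving 2.5 Å, say) the wRMSD is compressed
  relative to an unweighted RMSD because the moving half is down-weighted.
  Family-level thresholds in this package are therefore calibrated on the
  wRMSD scale, not on unweighted-RMSD conventions.

## Site reconstruction and sanity rules

`cluster_catalytic_residues()` finds every residue in the structure matching
a reference slot by (residue name, author number), seeds a cluster at the
first unassigned hit in (chain, number) lexicographic order, and grows it
greedily by adding, over all unfilled slots, the candidate closest to the
cluster's centre of mass (heavy atoms, unit masses; ties broken by lower
(chain, number)). Symmetric interface sites (two subunits each contributing
an equivalent residue pair) are disambiguated by the equivalence-group
identifier carried in the annotation, so one C2 site is reconstructed
rather than two half-sites. The deterministic seeding makes the output
invariant to atom/chain enumeration order, which is asserted in the tests.

Reconstructed sites are validated (`check_site_sanity()`): any
inter-residue centre-of-mass distance above 8 Å must be at most 3 times the
corresponding reference distance, and at most 1.3 times the equivalent
distance in every sibling site of the same structure (the sibling rule
carries no 8 Å gate). Surviving sites pass redundancy reduction
(`deduplicate_sites()`): greedy in input order, dropping any site within
0.5 Å wRMSD of an already retained one — 0.5 Å being the estimate of
coordinate uncertainty used as the rigid/flexible boundary throughout.

## Ligand identification and classification

Adjacent components are found within 3 Å of any catalytic atom; residue
pairs whose centres of mass lie more than 6 Å apart additionally contribute
a pseudo-centre at the average of the two centres of mass, filling the
search gap between distant residues. Polymer residues from chains not
contributing to the site are merged into one `POLYMER` record per chain.
Distal cofactor-like and substrate-like components are reported within 30 Å
of the site centroid.

Chemical similarity (`parity_similarity()`) is the proportion of atoms
residing in identical topology: with $m$ the atom count of the maximum
common connected substructure (elements must match, bond orders are
ignored), the score is $m / (n_a + n_b - m)$. The MCS engine is an exact
branch-and-bound search, pluggable through the `engine` argument, and is
verified in the tests against an exhaustive subset-enumeration oracle. The
score is undefined (null) for single-atom components and polymers.

Classification applies, in order: substrate-like if the best similarity to a
cognate reaction component is ≥ 0.6; cofactor if the component code is in
the cofactor table (metals and other single-atom components land here);
artefact if the code is in the crystallisation-artefact table and the best
similarity does not exceed 0.3; otherwise uncertain. Both tables ship as
editable TSV files under `inst/extdata/`. Each ligand also gets a
*centrality*: its mean distance to the residue centres of mass, normalised
by the mean inter-residue distance — values near or below
$1/\sqrt{3} \approx 0.58$ (the centroid of an equilateral triad) indicate a
ligand sitting amid the catalytic residues.

Note that a bond-order-blind MCS similarity is generous to small polyols:
glycerol scores 0.71 against pyruvate, well above the 0.3 artefact escape.
The artefact table therefore matters in practice, and the shipped fixtures
use sulfate (similarity 0.1 to a carboxylate cognate) as the canonical
artefact example.

## Family-level analyses

`family_pair_table()` runs all pairwise superpositions, carrying per-pair
metadata; `apply_pair_filters()` implements two clean-up profiles with every
exclusion logged by rule tag. The *seq_struct* profile: resolution ≤ 2.0 Å,
no NMR structures, RMSD ≤ 10 Å, and at most 30 comparisons per family by
seeded random sampling. The *ligand_effect* profile: the same
resolution/NMR rules plus no missing EC number, no gapped sites, mean
intra-residue distance discrepancy ≤ 5 Å, wRMSD ≤ 10 Å, maximum
single-residue RMSD ≤ 20 Å, and exclusion of suspect fits with wRMSD > 1.5 Å
whose maximum residue RMSD exceeds 3× the wRMSD. The whole-protein RMSD cap
of the sequence/structure analyses is applied to the active-site Cα RMSD
here, since whole-chain alignment is outside this package's scope.

Pairs are grouped by protein identity (equality of the sequence accession in
the annotation), catalytic-residue conservation, and ligand state — a site
is *bound* if it has at least one adjacent non-artefact, native-like
component (substrate-like or cofactor) — with per-family mean wRMSD in each
of the twelve buckets.

Conformer clustering is average-linkage (UPGMA) on the all-vs-all wRMSD
matrix, pruning the dendrogram at 0.4 times the maximum merge height (with
a 1e-9 epsilon so numerically-zero heights collapse identical sites into one
cluster). `NA` cells are imputed with the matrix maximum and logged.

Pair-level flexibility is summarised in quadrants at the 0.5 Å
experimental-error limit, comparing main-chain (Cα) and functional-atom
RMSD; *flexible* is inclusive (≥ 0.5 Å). Residue-level enrichment samples up
to 50 superpositions per family (seeded), splits residue records at the same
0.5 Å limit, and reports flexible-over-rigid frequency odds ratios per
residue type, role and role category, suppressing groups under 2% of the
sampled records and marking rigid-empty groups with an infinite ratio.

## The paradigm classifier

Families with at least 50 homologous sites are classified from the
distribution of their all-vs-all wRMSD values; smaller families are
`unclassified` (the handling of families between 2 and 49 sites is a
deliberate floor, not a statistical claim). The rule, with thresholds in
`paradigm_thresholds()`:

1. **open/closed** — a 2-component Gaussian mixture beats 1 component by
   more than 10 BIC *and* the components separate by more than 5 pooled
   standard deviations;
2. **extensively variable** — moderate multimodality (separation > 2 pooled
   sigmas) or overdispersion (sd > 0.5 × mean);
3. **inherently rigid** — mean wRMSD < 0.5 Å;
4. **inherently flexible** — otherwise.

The thresholds were calibrated once on the synthetic presets at the study
conditions (50 sites per family): clean two-state ensembles separate their
mixture components by 6–14 pooled sigmas, drifting ensembles by 2.7–4,
unimodal ensembles stay under 1.8; rigid ensembles centre near 0.2 Å and
flexible ones near 0.75 Å, so the 0.5 Å boundary splits them with a wide
margin. Distribution skewness is recorded in the call's statistics but is
not used as a gate — on the wRMSD scale it does not discriminate between
the presets. All mixture fits use `mclust`; a failed fit degrades to the
dispersion rules rather than erroring.

## What the synthetic generator emulates — and what it does not

`generate_site_ensemble()` builds an idealized reference site (templated
residue geometries on a 5 Å ring) and homologues as the reference plus
per-residue rigid displacements, followed by a random rigid motion of the
whole site:

* **rigid**: isotropic N(0, 0.1 Å) displacement per residue;
* **flexible**: per-slot σ drawn once from U(0.5, 1.5) Å;
* **two_state**: half the slots shift coherently by 2.5 Å in half the
  sites (each site drawn open/closed with probability 0.5);
* **extensive**: half the slots drift by a per-site random walk of step
  1.0 Å;
* a **bound/free** variant perturbs bound sites with σ = 0.1 Å and free
  sites with σ = 0.5 Å, emulating stabilisation upon ligand binding.

Ground truth (per-slot displacement magnitudes, states, bound flags) is
recorded on the returned object. `generate_assembly()` builds multi-chain
structures — separated homodimer sites, C2 interface sites with
equivalence groups, optional mis-numbered decoy residues, and ligands placed
relative to the site centroid — and writes them as PDB, mmCIF and
annotation JSON.

The generator emulates *rigid-body residue displacements with idealized
internal geometry*. It does not emulate: rotamer changes (atoms within a
residue move together), anisotropic or resolution-dependent coordinate
error, missing atoms/occupancy pathologies, correlated domain motions beyond
the coherent two-state shift, or crystal-contact artefacts. Tests passing on
these fixtures therefore demonstrate the correctness of the algorithms under
their stated geometric assumptions — not that real crystallographic
ensembles will show the same recovery rates.

## Problem sizes and reproducibility

The test suite and the acceptance script classify 50 ensembles per preset of
50 sites each (1,225 superpositions per ensemble), which keeps the full run
in the minutes range on a single core; smaller fixture sizes are used where
only correctness, not distributional behaviour, is asserted. Every source of
randomness is driven by an explicit seed: generator specs carry one, the
sampling filters take one, and the command-line pipeline derives all of its
sub-seeds from the config seed, making whole-pipeline reruns bit-identical
(the provenance header of every output embeds the package version and a hash
of the resolved configuration).

## Known limitations

* The exact weight kernel and convergence rule of the published
  Gaussian-weighted fits vary across the literature; this implementation
  fixes $w = \exp(-d^2/c)$ with $c = 2$ Å² and documents the c → ∞ limit as
  an invariant. Comparisons across packages should calibrate on shared
  fixtures.
* The MCS-based similarity ignores bond orders and charge, which inflates
  scores between small oxygen-rich molecules (see the glycerol example
  above).
* Per-residue RMSDs are measured in the frame of the weighted fit; when
  *every* residue is mobile the frame itself is uncertain, and per-residue
  values are correspondingly noisy (the slot-level averages remain
  accurate, which is what the enrichment analysis consumes).
* The paradigm classifier is a formalisation of a qualitative taxonomy; its
  thresholds are calibrated to this package's wRMSD scale and should be
  re-examined if `c_param` is changed.
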