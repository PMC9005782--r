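# sitevar

Structural comparison of enzyme active sites across homologous crystal
structures: reconstruction of catalytic sites from multi-chain assemblies,
symmetry-aware Gaussian-weighted superposition over functional atom triads,
ligand classification by chemical similarity, and family-level
characterisation of conformational behaviour.

`sitevar` is aimed at structural bioinformaticians studying catalytic-residue
flexibility: given a curated reference site (catalytic residues with chain,
author numbering, functional role, and an equivalence-group id for symmetric
interface sites) and a set of homologous structures, it answers questions
like *which residues of this family move, by how much, and does ligand
binding stabilise the site?*

## The method

Each catalytic residue contributes a **functional atom triad** — three atoms
of the moiety performing its chemistry (e.g. Arg: CZ, NH1, NH2; main-chain
function: N, CA, C). Two homologous sites are aligned by:

1. residue pairing with mutation handling — conservative mismatches
   (Asp↔Glu, Asn↔Gln, Ser↔Thr↔Tyr, Val↔Leu↔Ile) pair chemically analogous
   atoms, non-equivalent mismatches wildcard the whole triad, gaps are
   excluded;
2. a crude Kabsch fit, then Kuhn–Munkres (Hungarian) assignment inside every
   exchangeability class (Asp/Glu terminal oxygens, His ring atoms, ...) so
   flipped side chains superpose exactly;
3. an iteratively reweighted Kabsch fit with Gaussian weights
   *w<sub>i</sub>* = exp(−*d<sub>i</sub>*² / *c*), reporting

   wRMSD = √( Σ *w<sub>i</sub>* *d<sub>i</sub>*² / Σ *w<sub>i</sub>* )

   plus unweighted per-residue RMSDs under the final transform. The weights
   lock the fit onto the invariant core, so a single mobile residue shows
   its true displacement instead of smearing it over the site.

Family-level tools build all-vs-all wRMSD matrices, apply the documented
clean-up filters, cluster conformers (UPGMA, dendrogram pruned at 0.4 × the
maximum merge height), classify each family as **inherently rigid /
inherently flexible / open–closed / extensively variable**, split pairs into
flexibility quadrants at the 0.5 Å experimental-error limit, and compute
flexible-over-rigid enrichment odds ratios per residue type, role and role
category. A synthetic-fixture module generates structures, annotations and
conformer ensembles with known ground truth, so everything runs and tests
without downloads. See the methods vignette
(`vignettes/active-site-variation.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(sitevar)

## a synthetic homodimer with a lactate ligand near each site
asm <- generate_assembly(
  "homodimer",
  ligands = list(list(comp_id = "LAC", offset = c(0, 0, 2))),
  seed = 42)
sites <- build_active_sites(asm$struct, asm$family)
sites[[1]]
#> <active_site syn_homodimer_1_site1> structure syn_homodimer_1: 3/3 slots filled
#>   [1] A SER10 (side_chain, reactant, equiv 0)
#>   [2] A HIS20 (side_chain, reactant, equiv 0)
#>   [3] A ASP30 (side_chain, spectator, equiv 0)

annotate_ligands(sites[[1]], asm$struct,
                 cognates = default_molecules()["PYR"])
#>   comp_id proximity   ligand_class best_match similarity centrality
#> 1     LAC  adjacent substrate_like        PYR          1  0.6345537
```

The lactate is substrate-like: it scores 1.0 against the cognate pyruvate
(identical heavy-atom topology) and sits amid the catalytic residues
(centrality 0.63, where 0.58 is the centroid of an equilateral triad).

```r
## a two-state family: 50 homologous sites, half open, half closed
fam <- generate_site_ensemble(ensemble_spec("two_state", n_sites = 50,
                                            seed = 7))
m <- all_vs_all_matrix(fam$homologs)
classify_paradigm(m[upper.tri(m)], n_sites = 50, family_id = fam$family_id)
#> <paradigm_call SYN_two_state> open_closed (mean 0.41 A, sd 0.22,
#>   skew -0.03, dBIC 2464.6, sep 10.8, 1225 pairs)

table(cluster_sites(m)$labels)
#>  1  2  3
#> 25 24  1
```

The bimodal wRMSD distribution (two mixture components 10.8 pooled sigmas
apart) is called open/closed, and pruning the dendrogram at 0.4 × the
maximum merge height recovers the two planted conformer groups.

```r
gaussian_weighted_superpose(fam$homologs[[1]], fam$homologs[[2]])
#> <superposition hom001 -> hom002> wRMSD 0.178 A over 18 atoms
#>   (3 iterations, converged); max residue RMSD 0.259 A
```

A command-line pipeline over the same functions ships in
`inst/cli/sitevar` (subcommands `simulate`, `build_sites`,
`annotate_ligands`, `superpose`, `analyze`, with YAML config, explicit
seeds, and provenance headers in every output).

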