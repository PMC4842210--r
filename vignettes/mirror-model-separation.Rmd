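---
title: "Separating properly oriented and mirror-image protein models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating properly oriented and mirror-image protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorsep)
```

## The model and its assumptions

Contact-map-based reconstruction recovers inter-residue distances but not
chirality: a distance matrix is invariant under reflection, so reconstructed
ensembles mix properly oriented models with mirror models whose helices have
inverted handedness. This package implements the statistics that separate
the two populations for all-α proteins, where the signal is strongest: a
right-handed α-helix has (φ, ψ) ≈ (−57°, −47°), its mirror sits at
(+57°, +47°) in the left-handed-α region, and empirical backbone
distributions are heavily asymmetric between the two.

Three families of per-model statistics are computed:

1. **Φ⁺ ratio** — the fraction of positive φ among defined φ. φ = 0 counts
   as non-positive (a measure-zero tie read strictly). For a right-handed
   native the proper group has ratio ≈ 0 and the mirror group ≈ 1; for a
   left-handed native the interpretation flips, which is why the
   reference-free separator takes a handedness flag.
2. **Ramachandran statistics** — region fractions (favored / allowed /
   outlier, always summing to 100%) and two knowledge-based scores:
   `rama_score` = Σ −ln p(φ, ψ) per residue class, and `p_aa_p_score` =
   Σ −ln P(aa | φ, ψ bin). Both are pure functions of the dihedral series
   (and sequence), so they need no native structure — this is the property
   that makes them usable as mirror filters in a real prediction setting.
3. **Superposition labels** — CA RMSD after Kabsch superposition (proper
   rotations only; the determinant correction matters here, since an
   unconstrained least-squares fit would happily reflect) against the
   reference and against its ideal mirror image, the model labeled by the
   nearer of the two, with a 1e-6 Å tie tolerance producing `ambiguous`
   rather than an arbitrary side.

Group-level analysis then asks, per domain and per energy term, whether the
proper and mirror groups differ: a two-sided Mann–Whitney U test per cell
(exact enumeration when both groups have ≤ 8 models, tie-corrected normal
approximation otherwise), a normalized-mean map NMTᵢ = T̄ᵢ / maxⱼ |T̄ⱼ|
bounded in [−1, 1], Pearson correlations between per-domain chirality ratios
and structural difficulty, and the structural-difference ratio
mean RMSD(proper) / mean RMSD(mirror), which is near 1 exactly when RMSD
alone cannot tell the groups apart.

### Choice of test

The per-term test is not dictated by the underlying study design, which only
requires "significantly different between the groups". We use the two-sided
Mann–Whitney U at α = 0.05: score distributions of distorted models are
skewed and occasionally heavy-tailed (a single hinged arm changes a score a
lot), and a rank test is invariant under monotone transforms of a term — a
property the test suite verifies. A Welch t-test is available via
`term_significance(..., method = "welch")` for sensitivity analysis. No
multiple-testing correction is applied by default, since the output is read
cell-wise as a per-domain, per-term matrix.

## The Ramachandran tables

The bundled tables are **not** Rosetta's: they are built analytically (no
random numbers) from a Gaussian-mixture prior over the canonical basins —
right-handed α (weight 0.53), β (0.28), PPII (0.15) and left-handed α at low
weight (0.015) for general residues, a symmetric mixture for glycine, a
restricted one for proline, and a slightly β-shifted one for pre-proline
(any residue immediately before Pro, overriding the general class only).
Densities live on a 2° grid, normalized to unit mass and floored at 1e-6
per squared degree before −ln so that no conformation scores infinitely
badly. Region labels follow the contour logic of empirical Ramachandran
atlases: cells are ranked by density and the favored region is the smallest
set holding 70% of the probability mass, allowed extends it to 95%, the
rest is outlier. With these masses the left-handed-α basin of the general
class falls in *allowed* — visible but never favored — which is exactly the
asymmetry the mirror filter exploits.

The P(aa | bin) table uses 10° bins and Laplace pseudocount 1 on expected
counts from per-residue-type mixtures; glycine (symmetric) and, mildly,
Asn/Asp are the residue types with real left-handed-α propensity, so a
mirror model filled with helix-former residues at positive φ is exactly
where P(aa | bin) collapses.

Because the tables are analytic fixtures, **absolute** score values do not
match PyRosetta's rama / p_aa_p terms; only relative proper-vs-mirror
comparisons are meaningful, and those depend only on the
right-handed-dominant basin asymmetry shared by any empirical table.
`write_rama_tables()` / `read_rama_tables()` (and the `build-tables` CLI
subcommand) serialize them to CSV; they are rebuilt deterministically at
first use rather than shipped.

## What the synthetic generator emulates — and what it does not

`make_ensemble` builds a reference bundle in internal coordinates (NeRF
placement with fixed ideal bond lengths N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å), perturbs it to make proper models, and perturbs its mirror
image to make mirror models, each model carrying its construction label and
CA RMSD to the reference.

Design choices that were genuinely open, and why they were made:

- **Chirality-aware loop search.** Helix dihedrals are fixed at (−57, −47)
  (negated for left-handed natives); each loop is optimized over a seeded
  set of turn-conformer combinations by minimizing *Rg − 3 × RMSD(chain,
  its own mirror)*. Radius of gyration alone drifts to near-planar folds
  that are almost congruent with their own mirror image (ref-vs-mirror RMSD
  ~4 Å), which would make the mirror-detection problem ill-posed by
  construction; real all-α bundles are chiral objects 15–30 Å from their
  reflections, and the second term reproduces that. For the same reason the
  study-batch layouts use 3–4 helices: a two-rod hairpin is nearly planar
  and hence nearly mirror-symmetric at the fold level.
- **Crankshaft-correlated noise.** Dihedral noise is marginally
  N(0, σ²) per angle, but φᵢ₊₁ compensates ψᵢ with correlation −0.85
  across the peptide bond. Independent per-angle noise on a 100–160-residue
  chain accumulates into 10–20 Å whole-arm drift at σ = 4°, which no
  contact-map-constrained reconstruction shows; the correlated model keeps
  proper models in the realistic 2–9 Å band while leaving single-residue
  statistics untouched.
- **Outlier residues are free hinges.** With probability `outlier_fraction`
  a residue's (φ, ψ) jumps to a uniform draw, and the chain is rebuilt —
  one such hinge swings an arm by 10–30 Å. This is deliberately
  catastrophic: it is the mechanism that produces the indistinct regime.
- **Regime presets** (σ, outlier fraction): distinct (4°, 0), moderate
  (10°, 0.01), indistinct (22°, 0.25). They were calibrated once against
  the three target histogram shapes — non-overlapping proper/mirror RMSD
  distributions, overlapping-but-separable, and effectively unimodal — and
  then frozen. The distinct preset has no hinge outliers precisely because
  a single hinge already breaks non-overlap on chains of this length.
- **RNG streams.** All randomness derives from one master seed by counter
  (`derive_seed`), so identical specs reproduce byte-identical PDB output.

What a green test on synthetic data does **not** establish: the generator
has ideal bond geometry, no side chains, no β-structure, dihedral-only
noise, and an idealized chirality signal; it says nothing about
reconstruction pipelines' actual error models, about mixed-chirality
natives, or about absolute energy scales. It establishes that the
statistics behave as designed on ensembles with the assumed structure —
labels recoverable when RMSD separates, dihedral scores separating groups
even when RMSD does not (moderate regime), and everything degrading
honestly in the indistinct regime.

## Numerical choices

- Dihedrals live in (−180, 180]; the branch-cut neighbourhood (within 1e-9°)
  collapses onto +180 so antiperiplanar geometry cannot flip sign by
  rounding. Collinear point triples raise an error rather than returning an
  arbitrary angle.
- Chain breaks are detected by consecutive C–N distance outside [1, 2] Å;
  φ/ψ/ω spanning a break are undefined and silently skipped by every
  consumer (with an error only when *nothing* is classifiable).
- The Kabsch rotation is forced proper by the SVD determinant correction;
  degenerate (collinear) point sets warn and return one valid minimizer.
- Mirror reflection is canonically through the yz plane; any other improper
  operation differs from it by a proper rotation, which superposition
  absorbs.
- The exact Mann–Whitney path enumerates all C(n₁+n₂, n₁) rank splits and
  uses the symmetric two-sided definition P(|U − n₁n₂/2| ≥ |u − n₁n₂/2|);
  the approximate path applies tie correction and a 0.5 continuity
  correction.
- 1-D two-means in `separate_ensemble` initializes centers at the score
  minimum and maximum, making the split deterministic; identical scores are
  an error ("no separation") rather than an arbitrary partition.

## Known limitations

- All-β and mixed folds are out of scope (the chirality signal via helix
  handedness is absent); so are multi-chain assemblies, mmCIF input, and
  sequence-alignment superposition of unequal-length structures.
- The p_aa_p analog shares its basin prior with the rama analog, so the two
  scores are correlated on synthetic data by construction — more than
  Rosetta's independently derived tables would be.
- Orientation labels assume the reference and model have identical residue
  counts and ordering (reconstruction-pipeline output, not general PDB
  pairs).
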