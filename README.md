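# mirrorsep

Detecting and filtering mirror-image artifacts in protein structure
ensembles reconstructed from residue–residue contact maps.

## The problem

A contact map records which residue pairs are close in space, but distances
carry no chirality: the same map is satisfied equally well by a fold and by
its mirror image. Reconstruction pipelines therefore emit ensembles that mix
*properly oriented* models with *mirror* models whose α-helices are
left-handed. When the native structure is known, the two groups can be told
apart by superposition; in a real prediction setting it is not, so the
separation has to come from the models themselves. For all-α proteins the
backbone dihedrals carry the signal: right-handed helices have φ ≈ −57°,
ψ ≈ −47°, while mirror models pile up in the left-handed-α region
(φ > 0, ψ > 0) that empirical Ramachandran distributions strongly disfavor.

## What the package computes

For a model *m* with backbone dihedrals (φᵢ, ψᵢ):

- **Φ⁺ ratio** — #{i : φᵢ > 0} / #{i : φᵢ defined}, near 0 for right-handed
  folds and near 1 for their mirrors (`phi_plus_ratio`).
- **Ramachandran region fractions** — % of residues in favored / allowed /
  outlier regions, per residue class (general, Gly, Pro, pre-Pro)
  (`region_fractions`, `classify_region`, `count_lh_alpha`).
- **Dihedral knowledge-based scores** — `rama_score(m) = Σᵢ −ln p(φᵢ, ψᵢ)`
  and `p_aa_p_score(m) = Σᵢ −ln P(aaᵢ | φᵢ, ψᵢ)`, evaluated on bundled
  analytic tables with right-handed-dominant basins; lower is more
  native-like, and mirrors of right-handed folds score systematically
  higher.
- **Orientation labels** — `assign_orientation(m, ref)` superposes *m*
  (Kabsch, proper rotations only) on the reference and on its ideal mirror
  image and labels by the smaller CA RMSD; `separate_ensemble(scores)` is
  the reference-free 1-D two-means split.
- **Group statistics** — per-term Mann–Whitney significance between proper
  and mirror groups (`term_significance`, `significance_matrix`),
  normalized term means NMTᵢ = T̄ᵢ / maxⱼ |T̄ⱼ| in [−1, 1]
  (`nmt_normalize`), Pearson correlations (`pearson`) and per-domain
  structural-difference summaries (`domain_summaries`).
- **Synthetic ensembles** — `make_ensemble` / `make_study_batch` build
  labeled proper/mirror ensembles of noisy helical bundles in three
  difficulty regimes (distinct / moderate / indistinct RMSD separation), so
  the whole pipeline is testable without any structure download.

## Worked example

```r
library(mirrorsep)

batch <- make_study_batch(3, regime = "distinct", seed = 1,
                          n_proper = 10, n_mirror = 10)
tab <- score_ensemble(batch$domain_01)
head(tab[, c("model_id", "label", "rmsd_to_ref", "rama", "phi_plus_ratio")], 4)
#>    model_id  label rmsd_to_ref     rama phi_plus_ratio
#> 1 model_001 proper    3.885080 976.1183     0.03252033
#> 2 model_002 proper    3.095084 974.6960     0.03252033
#> 3 model_003 proper    1.611490 978.2091     0.03252033
#> 4 model_004 proper    3.305561 974.4206     0.03252033

sig <- significance_matrix(lapply(batch, score_ensemble))
sig$significant
#>            rama p_aa_p phi_plus_ratio
#> domain_01  TRUE   TRUE           TRUE
#> domain_02  TRUE   TRUE           TRUE
#> domain_03  TRUE   TRUE           TRUE
```

Every proper model sits a few Å from its reference with a low rama score
and Φ⁺ ratio near 0; mirror models sit 15–30 Å away with visibly higher
scores, and both dihedral terms separate the groups significantly in every
domain — the pattern the whole analysis is built to detect.

The end-to-end pipeline (labels, term values, significance matrix, NMT
maps, domain summaries, correlations) is one call:

```r
cfg <- run_config("simulate", out_dir = "out", n_domains = 11, seed = 1)
run_analysis(cfg)
```

A command-line interface with `simulate`, `classify`, `analyze` and
`build-tables` subcommands lives at `inst/cli/mirrorsep.R`
(`Rscript <path to mirrorsep.R> simulate --domains 11 --seed 1 --out dir/`).

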