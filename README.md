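# saxlink

Integrative structural analysis of protein complexes that bind and
oligomerize along double-stranded RNA.

Heterodimeric dsRNA-binding complexes such as NF45–NF90 change conformation
when they engage a duplex, pack laterally against neighbouring complexes, and
coat long dsRNA as "beads on a string". No single technique proves this:
the case is built from solution SAXS (does the complex compact?), quantitative
cross-linking mass spectrometry (which residue pairs approach each other only
on RNA, and are they compatible with one copy or only with two?), population
missense-variant depletion (which domains are functionally constrained?), and
single-particle counting (how many proteins per duplex, how far apart?).
`saxlink` implements each of these analyses as tested R functions, plus
seeded synthetic-data generators so every statistic has a ground-truth
recovery test. It is written for structural biologists and computational
biologists who need the quantitative steps of such an integrative study to be
scripted, reproducible and auditable.

## What it computes

**Solution SAXS.** SEC frame reduction (buffer subtraction with error
propagation); Guinier fits of ln *I* vs *q*² on the largest window with
*q*·*R*g ≤ 1.3 (so *R*g = √(−3·slope), *I*₀ = exp(intercept)); the
pair-distance distribution *P*(*r*) by regularized indirect Fourier
transform — minimize ‖(*I* − *A p*)/σ‖² + α‖D₂*p*‖² with *p* ≥ 0 and
*p*(0) = *p*(*D*max) = 0 — with an explicit *D*max scan rule; dimensionless
Kratky transforms (*qR*g)²·*I*/*I*₀ (compact particles peak at (√3, 3/e));
molecular weight from the volume of correlation
*V*c = *I*₀ / ∫ *q I*(*q*) d*q*, *QR* = *V*c²/*R*g, MW = (*QR*/0.1231) Da;
Debye theoretical curves from coordinates; and sparse multi-state fits that
pick the fewest candidate states whose reduced χ² is within 5% of the best.

**Quantitative CLMS.** Fold-change classification of cross-linking features
between two conditions (enriched at ≥ 2-fold, common otherwise,
presence/absence detections flagged); minimal Cα–Cα distances over model
copies, chain assignments and crystallographic symmetry mates against the
24 Å EDC contract; and competitive scoring of assembly hypotheses (one
heterodimer vs a lateral oligomer) by satisfied-link fraction.

**Variant depletion.** The domain statistic *V*d/*V*p — variant density in a
domain over the whole-protein density, after removing pathogenic/ClinVar
variants; values below 1 flag constrained domains.

**Stoichiometry and footprint.** Gaussian-mixture peak fitting of
mass-photometry events; exhaustive (protein, RNA) composition assignment;
the steric footprint interval from occupancy observations — at most *k*
sandwiching pairs on an *L*-bp duplex constrains the per-pair footprint to
(*L*/(*k*+1), *L*/*k*] bp, intersected across duplex lengths; lateral
oligomer building with clash checks; and bead-on-string spacing statistics.

## Worked example

```r
library(saxlink)

# simulate a SEC-SAXS measurement of a compact 100 A particle
sim <- gen_curve("sphere", list(R = 50), noise_rel = 0.01, seed = 1)
g <- guinier_fit(sim$curve)
est <- estimate_dmax(sim$curve, dmax_grid = seq(60, 140, by = 5))

# classify planted RNA-enriched cross-links and test the 24 A contract
model <- make_fixture_structure("cloud", n_res = 60, radius = 30, seed = 7)
xl <- gen_crosslink_table(model, n_true = 10, n_decoy = 10,
                          planted_fc = c(rep(4, 5), rep(1, 15)), seed = 7)
cls <- classify_quant(xl$features, c("control", "rna"))
dist <- map_distance(cls, model, chain_map = list(P1 = "A"))

# steric footprint from a duplex-length occupancy ladder
fp <- footprint_interval(list(c(25, 1), c(36, 1), c(54, 2)))
```

This prints:

```
Rg = 39.62 A (truth 38.73), I0 = 100.6
Dmax = 100 A (truth 100), P(r) fit chi2 = 0.91

  A_enriched   B_enriched       common unquantified
           0            5           15            0
10/20 links satisfy the 24 A Calpha-Calpha contract
footprint per sandwiching pair: (18, 25] bp
```

The Guinier radius lands within 2% of the sphere value *R*√(3/5); the *D*max
scan recovers the 100 Å diameter exactly; all five planted 4-fold-enriched
links are called `B_enriched` (the RNA condition); exactly the ten links
sampled below 24 Å satisfy the distance contract; and the occupancy ladder
(one pair on 25 bp, one on 36 bp, two on 54 bp) pins the per-pair footprint
to (18, 25] base pairs — about 51–70 Å of duplex at the A-form rise of
2.81 Å/bp.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study on
synthetic data and write tables under `results/`:

| script | output |
| --- | --- |
| `01_simulate.R` | all synthetic inputs + truth records (`results/data/`) |
| `02_saxs_solution.R` | Guinier/Dmax/Kratky/MW per sample (`saxs_summary.tsv`) |
| `03_crosslink_quant.R` | categories, distance report, assembly ranking |
| `04_variant_depletion.R` | per-domain Vd/Vp (`depletion_ratios.tsv`) |
| `05_stoichiometry_footprint.R` | mass peaks, compositions, footprint, beads |
| `06_pipeline.R` | the same stages via the config-driven `run_pipeline()` |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

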