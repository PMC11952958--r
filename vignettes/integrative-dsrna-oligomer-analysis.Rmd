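---
title: "Methods: integrative analysis of protein oligomerization on dsRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of protein oligomerization on dsRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxlink)
```

`saxlink` implements the computational core of an integrative workflow for
deciding whether a protein complex compacts on double-stranded RNA and
oligomerizes along it. Four independent lines of evidence are combined:
solution SAXS (size, shape and mass of the free and RNA-bound complexes),
quantitative cross-linking mass spectrometry (which residue pairs come close
only in the RNA-bound state), population missense-variant depletion (which
domains are functionally constrained), and single-particle observables
(mass-photometry stoichiometries and negative-stain bead-on-string
measurements). Every stage is exercised end-to-end on seeded synthetic data
with machine-readable ground truth, so each statistic in the pipeline has a
recovery test.

## Solution SAXS

### Reduction and Guinier analysis

SEC-SAXS frames on a common q grid are reduced as `mean(sample) -
mean(buffer)`, with uncertainties propagated in quadrature and divided by the
frame counts; mismatched grids are an error rather than being silently
interpolated. The Guinier fit is a weighted linear regression of
$\ln I$ on $q^2$, with weights $(I/\sigma)^2$ (the delta-method variance of
$\ln I$). The fitted window is the largest low-q stretch satisfying
$q_\mathrm{max} R_g \le 1.3$, iterated to self-consistency from an initial
10-point window; 1.3 is the conventional globular-particle limit. A
non-negative slope (rising low-q intensity, e.g. aggregation) returns an
explicit failure status rather than an imaginary $R_g$.

### P(r) by regularized indirect Fourier transform

The pair-distance distribution solves

$$\min_{p \ge 0}\; \left\|\frac{I - A p}{\sigma}\right\|^2
  + \alpha \|D_2 p\|^2, \qquad
  A_{ij} = 4\pi\,\Delta r\,\frac{\sin(q_i r_j)}{q_i r_j},$$

on a uniform 51-point grid with $p(0) = p(D_\mathrm{max}) = 0$ pinned, where
$D_2$ is the second-difference (Tikhonov) smoother. The penalty block is
scaled by $\sqrt{\sum A_w^2 / \sum D_2^2}$ so that $\alpha$ is comparable
across data sets and $D_\mathrm{max}$ candidates. The non-negative
least-squares subproblem uses the Lawson–Hanson active-set algorithm, with a
cyclic coordinate-descent fallback for the rare systems where the active-set
iteration cap is exceeded. When $\alpha$ is not supplied it is chosen by the
L-curve corner (the point farthest from the chord between the extremes of the
log-residual / log-roughness curve) over the grid $10^{-8} \dots 10^{2}$.

### Dmax selection

Interactive IFT programs pick $D_\mathrm{max}$ by perceptual criteria; this
package uses an explicit, reproducible rule instead. Over a user-supplied
scan grid (5 Å steps in the analyses here), the selected value is the
*smallest* candidate whose constrained fit $\chi^2$ lies within a factor 1.05
of the scan minimum **and** whose unconstrained (ridge-only, free-tail)
solution is non-negative at $D_\mathrm{max}$ within 10% of its peak height.
The first condition rejects truncation (too-small $D_\mathrm{max}$ raises
$\chi^2$ steeply); the second rejects over-extension (too-large
$D_\mathrm{max}$ forces the free tail negative). The scan uses a fixed light
smoothing ($\alpha = 10^{-4}$) so that $\chi^2$ values are comparable across
candidates; re-selecting $\alpha$ per candidate would confound the scan. On
1%-noise synthetic data this recovers a 100 Å sphere exactly and a 120 Å
dumbbell within one scan bin; on heavily background-dominated data the
long-distance constraint weakens and the rule biases low, which the SEC
analysis script demonstrates deliberately.

### Kratky, molecular weight, Debye curves and multi-state fits

The dimensionless Kratky transform $(qR_g)^2 I/I_0$ vs $qR_g$ is pointwise
with no smoothing; a compact globular particle peaks at
$(\sqrt 3, 3/e)$. Molecular weight uses the volume of correlation
$V_c = I_0/\int q I(q)\,dq$ (trapezoid over the measured range, the $[0,
q_\mathrm{min})$ head integrated analytically under the Guinier model, upper
limit 0.3 Å$^{-1}$ matching the calibration range of the constants), then
$QR = V_c^2/R_g$ and the empirical protein power law $\mathrm{MW(Da)} =
(QR/0.1231)^{1.0}$ (RNA: $c = 0.00934$, $k = 0.808$). The estimator's method
name and constants are attached to every result because the law is calibrated
on globular proteins and is only indicative for protein–RNA complexes. An
absolute-$I_0$ calibration mode ($\mathrm{MW} = I_0/k_\mathrm{inst}$) is
provided for instruments with a known scale constant.

Theoretical curves from coordinates use the Debye formula with one constant
form-factor bead per residue (the Cα, or the residue centre where no Cα
exists); the $q \to 0$ limit $(\sum f)^2$ and the self term are handled
analytically. Multi-state fitting enumerates candidate subsets up to
`max_states`, solves non-negative weights by NNLS on the σ-weighted system,
and reports the best subset of the smallest size whose reduced $\chi^2$
($N-1$ degrees of freedom, the FoXS convention) is within 5% of the global
best — the "fewest states that fit" rule. Candidate curves may be supplied as
profiles or generated from coordinates; no conformer sampling is performed.

## Quantitative cross-linking MS

A cross-linking feature is a residue pair with replicate MS1 areas per
condition. Fold change is the ratio of the means of non-missing areas
(`rna / control` in the analyses here); a feature is enriched in a condition
at a two-fold threshold, `common` otherwise. Features detected in only one
condition (at least 2 replicates there, none in the other) are assigned to
that condition's enriched class with an infinite/zero fold change and an
explicit flag — presence/absence differences are evidence, not missing data.
Missing values are never imputed, and the classification is the pure
fold-change rule; a Welch t statistic is attached per feature as a clearly
labelled extension. The rule is symmetric: relabelling the conditions swaps
the enriched classes exactly. (The source data format describes both enriched
classes with the same wording for the control group — an evident typo; the
intended meaning, intensity higher in the respective group, is implemented.)

Distance validation anchors each site at its Cα and asks for the minimal
Cα–Cα distance over all supplied model copies, all chains its protein maps to
(homodimeric ambiguity resolved by the minimum over assignments), and — for
crystal structures — all symmetry mates. Site A is held in the identity copy
while site B is enumerated over every operator and integer lattice shift in
$[-2, 2]^3$; because the relative placements of a space group form a group,
this covers all copy pairs. EDC is a zero-length chemistry, but flexibility
of side chains and backbone justifies the conventional 24 Å Cα–Cα allowance
used as the default satisfaction contract (configurable). Competing assembly
hypotheses (e.g. one heterodimer vs a lateral two-copy assembly) are ranked
by satisfied fraction, ties broken by the mean distance of violated links.

## Missense-variant depletion

The domain depletion statistic is the ratio of variant densities,
$V_d/V_p$: unique variants per residue inside the domain over unique variants
per residue across the whole protein. Values below 1 indicate local
depletion. A variant is a unique (position, amino-acid change) pair by
default (`unit = "position"` switches to unique positions); allele
frequencies are not weighted. Likely pathogenic and ClinVar-flagged variants
are removed before the ratio is computed, since the statistic is about
*benign* variation tolerated by the population. Note that $V_p$ includes the
depleted domain itself, so with a planted rate factor $f$ over a domain of
length $L_d$ in a protein of length $L$ the expected ratio is
$f / ((L_d f + (L - L_d))/L)$, not $f$; the recovery tests invert this
relation to check the planted factor. Domain boundaries are user-supplied.

## Stoichiometry, footprint and bead strings

Component masses use average amino-acid residue masses plus one water
(free glycine = 75.07 Da) and an average 320.5 Da per nucleotide residue for
duplex RNA (a 54-bp duplex is 34.6 kDa), with a sequence-exact override.
Mass-photometry events are fit with a 1-D Gaussian mixture (`mclust`,
unequal variances; BIC-selected component count in auto mode, bounded at 6,
requiring at least 50 events). Compositions $(n_\mathrm{protein},
n_\mathrm{RNA})$ up to 10 copies each are enumerated exhaustively; a peak is
assigned the composition with the smallest residual within tolerance, ties
broken by fewer total copies, then fewer proteins.

The steric footprint model assumes complexes bind the duplex as sandwiching
pairs (two complexes per duplex cross-section, one on each face), so
occupancy observations are expressed in pairs, with a helper converting
complex counts by ceiling division. An observation "at most $k$ pairs on an
$L$-bp duplex" constrains the per-pair footprint to $(L/(k+1), L/k]$; the
estimate is the intersection over observations, and contradictory
observations yield an explicitly flagged empty interval rather than an error.
The occupancy ladder used in the analyses — one pair on 25 bp, one on 36 bp,
two on 54 bp — intersects to (18, 25] bp. Conversions between base pairs and
Ångström use the A-form helical rise of 2.81 Å/bp (configurable). Lateral
oligomer models are built by applying a rigid step (a rise along an axis, or
an explicit transform) cumulatively; the clash report counts inter-copy
heavy-atom pairs under 2.5 Å. Bead-on-string statistics pool
consecutive-centre distances within each annotated string and summarize
spacing, bead length and bead width, with declared units (Å or nm).

## Synthetic data: what it emulates, and what it does not

Generators exist for every input: scattering curves from closed-form shapes
(sphere, dumbbell) or coordinates, SEC frame stacks with a flat buffer
background, Cα-only fixture structures (helix, cloud, two-domain) and a toy
P2₁-like crystal, two-condition cross-link tables with planted fold changes
and planted true/decoy distances, variant tracks with planted per-domain
depletion factors, mass-event mixtures from known stoichiometries, and
jittered collinear bead strings. Every generator takes an explicit seed, is
bit-reproducible, and emits a truth record the tests consume. One global seed
fans out to named streams via a documented polynomial-hash rule
(`sub_seed`), so composed scenarios stay uncorrelated.

Default conditions: 1% relative Gaussian noise with a small floor on
scattering curves (the shape of counting statistics without a detector
model); 3 replicates at 20% CV, log-normal areas, for cross-link
quantitation; baseline 0.2 variants per residue; mass error σ = 8 kDa;
bead spacing 165 ± 10 Å with bead length 160 ± 15 Å and width 130 ± 15 Å,
matching negative-stain observations of paired complexes on long duplexes.

The synthetic data deliberately omit several features of real measurements:
instrumental smearing and inter-frame drift in SAXS, peptide-level
detectability bias and charge-state effects in CLMS, mutational spectrum
heterogeneity and coverage variation in population variant data, and
mass-photometry contrast-to-mass calibration error. Passing recovery tests
therefore demonstrate the correctness of the estimators under their stated
noise models, not robustness to every artefact of real data.

## Numerical choices and degenerate inputs

- NNLS: Lawson–Hanson first, cyclic coordinate descent (tolerance
  $10^{-10}$ relative, 2000 sweeps) as fallback.
- Guinier needs ≥ 5 positive-intensity points; curves are validated for
  strictly increasing positive q; a heuristic flags probable nm⁻¹ data
  (qmax > 2) with a conversion hint.
- Zero variants make $V_d/V_p$ undefined: an explicit status, not NaN.
- Stoichiometry peaks with no composition within tolerance produce an
  explicit unassigned record.
- Altloc conformers: highest occupancy wins, ties broken by altloc letter.
- Hydrogens are excluded from distance computations; author residue
  numbering is the only public addressing scheme.
- Identity steps in oligomer building return the assembly with a clash
  failure flag rather than erroring, so callers can inspect the geometry.

## Problem sizes

The shipped analyses and tests run on: 296-point q grids, 51-point IFT
grids and 17-candidate Dmax scans; 60-residue cross-link fixtures with
10 + 10 links, 100-seed sensitivity sweeps; 500-residue variant tracks over
500–1000 seeds; 4000 mass events; 50 strings × 5 beads. These sizes keep the
full suite under half a minute while leaving Monte-Carlo standard errors
well inside the asserted tolerances.

## Known limitations

No ab initio bead modelling, SEC peak deconvolution, absolute-scale
calibration, conformer sampling, cross-link FDR estimation or micrograph
processing: upstream tools' outputs (curves, intensity tables, tracks,
annotated measurements) are this package's inputs. The MW power law and the
24 Å contract are field conventions, surfaced as explicit, overridable
constants rather than hidden defaults.
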