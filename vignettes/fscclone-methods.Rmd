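---
title: "Models and methods behind fscclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fscclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscclone)
library(dplyr)
```

`fscclone` models mitotic-recombination lineage tracing of follicle stem
cells (FSCs) in the *Drosophila* ovariole. This vignette is the package's
account of its science: the models and their assumptions, the parameters
that matter, what the synthetic-data generators emulate (and do not), the
numerical choices, and the known limitations.

## Marker combinatorics

Each marking system is a set of chromosome arms carrying two
homolog-distal alleles around an FRT site. After Flp-mediated
recombination and mitosis, a daughter cell carries an unordered allele
pair per arm. The **equal-genotype model** — the assumption under which a
dual-FRT three-colour system yields six marker combinations at
1:1:1:2:2:2 — takes the three possible pairs per arm (hom1/hom1,
hom1/hom2, hom2/hom2) to be equally likely, independently across arms:

```{r}
phenotype_distribution(marking_system("LGR"))
```

Phenotypes follow a dominance rule (a marker is expressed iff at least
one copy is present); MARCM inverts this at the repressor, labelling only
cells with homozygous repressor loss. Because LacZ and GFP sit in *trans*
on the same arm (2L), every cell must express at least one of them;
`is_canonical_phenotype()` flags the RFP-only and triple-negative
combinations that no recombination event can produce — observing them
indicates marker silencing or another failure of the system.

The equal-genotype model is an assertion, not a mechanism. The
`chromatid_oracle()` therefore simulates (or enumerates exactly) G2
recombination at the chromatid level under explicit assumptions: which
chromatids pair at each FRT exchange, whether the two sites exchange
independently, and how sisters segregate. Under uniform pairing with
independent random segregation, a single-FRT exchange produces a
marker-homozygous daughter with probability 1/4 — not the 1/3 the
equal-genotype model implies — and the three-colour distribution departs
from 1:1:1:2:2:2:

```{r}
chromatid_oracle(marking_system("LGR"), segregation_assumptions(),
                 mode = "exhaustive")
```

The package treats the equal-genotype model as canonical (it is the basis
of the published frequency prediction) and keeps the oracle as an audit
tool; the `"equal_genotype"` segregation preset reproduces
`phenotype_distribution()` by construction. We deliberately do not
resolve which segregation rule is correct — the point is that the
prediction depends on it.

## Lineage timing

For `l` lineages whose cells all divide every `r` hours,
`P = l · 2^(t/r)`, so the time to reach `P` cells is
`t = log2(P/l) · r`. With `P = 900` (the Stage 6 cell count), `r = 9.6` h
and `l = 2`, `t ≈ 84.6` h (reported rounded to 85 h alongside the exact
value); `l = 16` gives ≈ 56 h. The model assumes synchronous exponential
growth with no early mitotic exit, so real times are slightly longer —
the polar/stalk sublineage stops dividing before Stage 6. Both directions
(`time_to_population()`, `population_after()`) are exact inverses.

## The germarium simulator

`simulate_ovariole()` is an event-driven continuous-time simulation of
one ovariole's scored region (germarium plus the youngest budded
follicles), with events processed in time order: heat shocks, background
recombination, FSC replacement, follicle buddings and samplings.

**Labelling.** `induction_prob` is the probability that the heat-shock
protocol as a whole visibly labels a given FSC or transit cell; it is
spread across the individual shocks as a per-shock hazard, so the
fraction of `l`-FSC ovarioles with an FSC clone is `1 − (1 − p)^l`
(0.339 at the default `p = 0.187`, `l = 2`). Labelled phenotypes are
drawn from the marking system's recombinant classes. Heat shock labels
in-transit (non-stem) cells as well as FSCs — this is what produces
transient clones and the elevated clonal diversity at early time points,
which then decays as transient clones traverse the ovariole and leave
the scored region after `ovariole_clearance_d` (8.5) days.

**Growth.** Each follicle is founded by one cell per active FSC and
grows toward the Stage 6 count of 900 cells at the 9.6 h cycle. Under the
default Polya-urn model each new cell joins a lineage with probability
proportional to the lineage's current size; for two founders the final
labelled share is uniform on (0, 1) — mean 1/2, which is why one labelled
FSC of two covers 50% of the epithelium *on average* while individual
ovarioles spread widely (SD ≈ 0.15–0.19 in simulated cohorts). The urn is
sampled through its exact de Finetti representation (symmetric Dirichlet
weights, then a multinomial for the remaining cells); the tests verify
equivalence against a literal sequential urn. A deterministic equal-split
mode exists for exact tests.

**Other processes.** FSC replacement (default 0.005/day per FSC)
truncates a lineage's border contact, leaving the multi-follicle,
non-border pattern expected of a recent replacement event. A labelled
transit cell may instead become quiescent (`quiescence_rate`, default
0.05) and sit in the germarium before detaching downstream — the
hypothesised origin of small-germarium and discontinuous patterns; this
is a modelling hypothesis, implemented as a rate, not an established
mechanism. Background recombination (default 2e-4 per division, chosen
to keep background induction under ~2% of ovarioles per week, as observed
for the GFP-negative system) creates heat-shock-independent clones, and
`silencing_rate` (default 0, intended for three-colour emulation)
heritably removes one expressed marker from a labelled lineage,
generating the anomalous combinations discussed above.

**Parameters without measured values.** The budding interval is not
directly measured; the default 12 h is a placeholder consistent with
several follicles in transit at once. The germarium is scored as 40
somatic cells, follicles bud at 30 cells, and 4 transit cells are exposed
to each heat shock — round numbers of the right order chosen once and
kept. Contiguity is represented logically (border flags, follicle spans,
contiguity links), not geometrically: the claim that FSC clones form
coherent patches is qualitative, and the simulator does not support
spatial detail it cannot justify. The anterior-most-cell annotation
reproduces the observed position frequencies (border / adjacent /
detached at roughly 85.7 / 7.9 / 6.3%) as generator defaults, since
these arise from escort-cell biology outside the model's scope.

## Clone statistics

`classify_clone_pattern()` assigns each recombinant phenotype in a record
to exactly one of five patterns. Precedence is explicit because the
categories are not mutually exclusive descriptions: discontinuity (a
border patch plus a detached same-phenotype patch downstream) is checked
first, as the decisive anomaly; then persistent (contiguous border patch
spanning ≥ 1 follicle), replacement (≥ 2 follicles, no border),
small-germarium (all patches inside the germarium), and transient
(≤ half of one follicle, no border; also the fallback). "Half of a
follicle or less" is evaluated on the labelled-cell fraction, not arc
length, because the simulator is non-geometric.

`count_unique_lineages()` counts marker-combination classes, not patches
— two disjoint patches of the same phenotype cannot be distinguished as
lineages without additional markers, so they count once; the unrecombined
class counts when unlabelled marked tissue is present. Frequency tables
(`tally_clones()`) are compared to model predictions with Pearson's
chi-square (`goodness_of_fit()`); the choice of test is ours — the
original comparison was descriptive.

## FSC-number inference

`estimate_fsc_number()` is the reciprocal-mean estimator: if one of `l`
equipotent stem cells is labelled, the labelled fraction has expectation
`1/l`, so `l̂ = 1/mean(fractions)` over mosaic ovarioles. Fully labelled
and unlabelled ovarioles carry no information about `l` under this design
and are excluded. No maximum-likelihood alternative is attempted — the
estimator is the one implied by the underlying reasoning. Uncertainty is
a percentile bootstrap over ovarioles (default 10^4 resamples, seeded);
`implied_fsc_range()` converts the mean ± 2 SD envelope into an FSC
range, clamping the lower fraction at `eps = 0.01` (flagged) because the
reciprocal diverges. The bounds are returned unrounded; interpretation
(e.g. "one to four") is left to the caller. Cross-condition clone-size
comparisons use Welch's t test with Bonferroni adjustment.

## Image quantification

`generate_stack()` renders nuclei as anisotropy-aware 3D Gaussian blobs
(σ = diameter/4, diameters drawn from 2.0–2.25 µm) at rejection-sampled
centres with a minimum spacing, in a two-channel volume (nuclear stain;
clone marker with bimodal per-nucleus amplitude), plus background and
Gaussian noise, with a full ground-truth table.

`segment_nuclei()` replaces an interactive surface-editing workflow with
reproducible rules: separable Gaussian smoothing; background subtraction
by a Gaussian blur at the nuclear-diameter scale (a high-pass, standing
in for a rolling-ball); global Otsu thresholding; seed detection at local
intensity maxima at least diameter/2 apart (the split rule for touching
nuclei); nearest-seed assignment of foreground voxels within one
diameter; and a minimum-volume quality threshold. A skewness-based guard
returns an empty result with a warning on blank images, where Otsu would
happily threshold noise. Neighbourhood sizes and the quality threshold
are exposed parameters whose defaults are justified only by
synthetic-data recovery (detection F1 ≥ 0.95, fraction error ≤ 2 points
on default stacks).

`fit_label_threshold()` automates the intensity-scatter step: exact Otsu
clustering of per-nucleus mean log-intensities (the split minimising
within-class variance), with a between/total variance ratio as a
bimodality diagnostic — degenerate unimodal inputs are flagged and left
unclassified rather than split arbitrarily. `quantify_clone_fraction()`
counts nuclei below/above the threshold in an anterior–posterior region
of interest, with the polarity set by the marking system.

Voxel conventions: 0-based physical coordinates with voxel-centred
positions (`(i − 0.5) · voxel size` µm for 1-based array index `i`), and
the anterior–posterior axis along +x.

## What the synthetic data do and do not show

The generators emulate the *statistical structure* of the experiments:
sparse induction, neutral exchangeable growth, transient-clone clearance,
replacement, background and silencing rates, bimodal marker intensities,
anisotropic sampling. They do not emulate tissue geometry, intensity
gradients, optical artefacts, cell-cycle synchrony after heat shock, or
any fitness difference between marked genotypes (marked lineages are
assumed neutral; the observed deficit of LacZ-negative clones suggests
real marker combinations are *not* equally fit). Passing recovery tests
therefore shows the pipeline is correct and calibrated under the model's
assumptions — it cannot show that real tissue satisfies those
assumptions. Empirical percentages from real ovarioles (clone-pattern
shares, anterior-cell positions, background rates) enter only as fixture
inputs or generator settings, never as quantities the package claims to
re-derive.

## Problem sizes and numerical choices

Simulated checks use cohorts of 150–300 ovarioles for calibration (10^4
for the induction-rate arithmetic), 2 000–3 000 draws for distributional
round trips, and default 200-nucleus stacks for the imaging pipeline —
sizes at which binomial 3-SE bounds are tight enough to be meaningful
while a full run stays interactive. Ties and degenerate inputs are
handled explicitly: zero-spread intensity vectors are unimodal by
definition; `fraction = 1` ovarioles are "full", not mosaic; empty
records classify as "no clone" rather than erroring; probabilities are
validated to machine tolerance (1e-12) where exact.
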