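---
title: "Quantifying inhibitory-synapse receptor trafficking with synaptiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibitory-synapse receptor trafficking with synaptiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
```

## What this package quantifies

Benzodiazepines potentiate GABA-A receptors that carry a gamma2 subunit, and
sustained exposure remodels the inhibitory synapse: receptors and their
gephyrin scaffold exchange faster with the extrasynaptic pool, more
receptors accumulate in intracellular vesicles and lysosomes, and the
receptor's protein interaction network shifts toward trafficking pathways.
`synaptiq` implements the measurement side of that biology as reusable,
tested code:

* **Puncta quantification** — segmentation of receptor/scaffold clusters,
  synaptic classification by presynaptic-marker (GAD65-type) colocalization,
  and decomposition of dendritic ROI intensity into synaptic,
  extrasynaptic and background parts.
* **FRAP exchange kinetics** — normalization of per-synapse
  fluorescence-recovery traces, cohort averaging, a two-pool exchange model,
  and treatment comparison by two-way ANOVA with Tukey contrasts.
* **Intersubunit FRET** — per-synapse donor/FRET/total-acceptor
  measurement, the four ordered restriction criteria, acceptor-photobleach
  efficiency estimation and the pH-quench specificity control.
* **Vesicle and lysosome scoring** — the surface/total reveal ratio, blob
  detection of large intracellular vesicles, new-vesicle counting, and
  receptor colocalization at lysosomes.
* **Co-IP interactome filtering** — spectral-count inclusion criteria,
  DZP/vehicle ratios with not-found sentinels, pathway-input fold-change
  conversion and a generic Fisher-exact overrepresentation test.

Because the raw microscopy and mass-spectrometry data behind these assays
are not publicly deposited, every stage is exercised against a
**synthetic-scene generator** whose ground truth is recorded, so that
segmentation counts, kinetic parameters, FRET efficiencies, vesicle counts
and planted interactome effects can all be scored against known answers.

## The synthetic-data generator

`scene_truth()` + `make_dendrite_scene()` render fields of isotropic
Gaussian puncta on a uniform background. Synaptic puncta are co-rendered in
a presynaptic-marker channel, which is exactly the information
colocalization-based classification is supposed to recover. Defaults follow
ordinary confocal practice for cultured cortical neurons: 0.1 um pixels, a
20 x 20 um field, punctum widths around sigma = 0.25 um (a few hundred
nanometres across, typical of inhibitory synapses), and peak-to-background
ratios near 20:1. Noise is shot noise approximated as a Gaussian whose
variance is proportional to the signal, plus additive read noise; intensity
is clamped at zero afterwards, a negligible distortion at the default
background of 10.

`simulate_frap()` draws recovery traces from the two-pool model described
below; `simulate_fret_pair()` and `simulate_bleach_series()` implement a
donor-quenching emission model (observed donor `D(1-E)`, sensitized
emission `A * E * coupling`, direct acceptor `A`); `simulate_vesicle_pair()`
renders paired pre/post vesicle fields in which the post image contains the
pre-image vesicles plus a known number of new ones; and
`simulate_spectral_counts()` draws weighted spectrum counts from a
gamma-Poisson (negative binomial) mixture with log-normal protein
baselines, per-sample library sizes, planted DZP/vehicle ratios, and IgG
control counts at a configurable fraction of the specific-IP mean.

What the generator does **not** emulate matters for interpreting green
tests: there is no point-spread-function physics beyond the Gaussian
profile, no focal drift, no uneven illumination, no autofluorescence
texture, no 3D structure, and spectral counts have no shared-peptide
ambiguity. Passing tests therefore demonstrate that the quantification
procedures are implemented correctly and are recoverable under realistic
noise — not that they are robust to every artifact of real microscopy.

## Puncta segmentation and intensity partitioning

Thresholding is the one step the original workflow performed interactively.
For reproducibility the default here is Otsu's criterion (maximizing
between-class variance over candidate intensity levels, at most 256 of
them) with a fixed-value override; the threshold actually used is always
recorded on the mask. A constant image has no valley to find and raises an
explicit degenerate-histogram error.

Connected components are 8-connected; components are kept when their area
lies in the half-open window (0, 3] square micrometres — the size-exclusion
window used for synaptic clusters — and have at least 2 pixels, an
automatic stand-in for interactive single-pixel cleanup. A receptor cluster
is *synaptic* when it shares at least one pixel with a marker cluster; the
overlap threshold is configurable because colocalization is not quantified
more precisely in the source workflow.

For a dendritic ROI the decomposition is

```
extrasynaptic = total - background * n_pixels - synaptic
```

so the three parts and the background reconstruct the ROI total exactly (a
machine-precision invariant in the test suite). The background estimator —
the median ROI intensity outside all clusters — is a documented choice; the
source workflow says only "minus background" without naming an estimator,
and a fixed value can be supplied instead. Cells are the experimental unit:
per-ROI summaries (typically three 10-um dendrite segments) are averaged by
`summarize_cell()`. A single outlier per data set may be removed by the
two-sided Grubbs test at alpha = 0.05 (`grubbs_remove_outlier()`), which
never iterates; the proprietary ROUT alternative is deliberately not
implemented.

## FRAP normalization and exchange kinetics

Each bleached synapse is normalized in two steps: post-bleach intensity
over pre-bleach intensity, then percent of the first post-bleach frame, so
every trace starts at exactly 100% and recovery beyond the bleach depth can
exceed 100%. That reporting scale diverges as the bleach gets deep
(I(0) -> 0), so all *fitting* happens on the pre-bleach-fraction scale

```
g(t) = b + m * (1 - b) * (1 - exp(-k t))
```

with bleach depth `b` in [0, 1), mobile fraction `m` in [0, 1] and exchange
rate `k >= 0` per minute. The recovery curves in the source study are
compared directly by ANOVA without a kinetic model; the single-exponential
two-pool model is this package's choice, adopted because it is the standard
reaction-dominant description of synaptic exchange and because the
simulator needs an explicit generative law.

Two estimators are provided. `fit_exchange()` fits one trace with bounded
Levenberg-Marquardt least squares and falls back to the boundary solution
`k = 0` for flat traces. `fit_exchange_cohort()` exists because of an
identifiability problem worth stating plainly: over a 30-minute window a
slow synapse (k around 0.02/min) traverses less than one time constant, and
`k` trades off against `m` so strongly that independent per-trace estimates
are skewed upward. Conditions imaged under one bleach protocol share `m`
and `b`, so the cohort estimator fits all group-averaged curves jointly
with shared `m`, `b` and one `k` per condition — the fast condition pins
the plateau — then re-fits only `k` per trace. In parameter-recovery
simulations at 5% noise this brings the median per-synapse rate within a
few percent of truth where independent fits miss by 15-20%.

Group comparison uses a two-factor fixed-effects ANOVA (treatment x time)
on the percent-of-t0 recoveries with Tukey honestly-significant-difference
contrasts overall and at each timepoint, computed with base R's `aov()` and
`TukeyHSD()`; the test suite checks the decomposition against hand-computed
sums of squares on a balanced toy table. Traces with gaps are rejected
rather than interpolated.

## FRET restriction criteria and controls

`apply_restriction_criteria()` applies the four acceptance rules strictly
in order: (1) at least 15 synapses measured per cell or the whole cell is
rejected; (2) the FRET:total-acceptor sum ratio must be strictly less than
one; (3) donor mean intensity at least 500 (boundary kept, "at least");
(4) donor sum at most 300% of the average donor sum. Two points were
genuinely open and are resolved here as documented choices: the ratio in
criterion 2 uses *sum* intensities as quoted, and the "average" in
criterion 4 is computed over the synapses that survived criteria 2-3 of the
same cell (the alternative — all measured synapses — changes only
borderline cases; the chosen population makes re-application of the
criteria a no-op, which the suite checks as an idempotence property).
Per-criterion drop counts are always returned for audit.

Acceptor-photobleach analysis estimates the transfer efficiency as
`E = 1 - pre/post` donor intensity, warns when the FRET channel fell by
less than half (incomplete bleach), and is invariant to global intensity
rescaling. Because a single bleach event estimates `E` from two short frame
averages, analyses here follow the assay design of several bleached
synapses per condition and average the per-event estimates. The pH-quench
control normalizes FRET-channel intensity under acidic saline to the
neutral-saline baseline: a surface-dependent signal collapses toward zero
while a bleed-through-only signal stays near one.

## Vesicle scoring

The nominal spot size is treated as the object *diameter* with default
0.75 um. The source text is internally inconsistent — it speaks both of a
"circumference" and of a "circular area" of about 0.75 um — so the
parameter is configurable and the choice is surfaced here rather than
hidden. Detection smooths at the nominal scale, thresholds at a stringent
intensity floor, labels 8-connected components, and keeps components whose
equivalent-circle diameter lies within 0.4-2x nominal and whose
circularity (minor/major axis from second moments) is at least 0.8; a 3:1
elongated object fails that check. Below the stringent-floor regime the
diameter window makes the accepted-spot count non-monotone in the floor —
the count-monotonicity property holds in the detector's operating regime
and the tests state it that way.

New vesicles are counted by greedy nearest-neighbour matching of post
spots to pre spots within 0.5 um, ties broken deterministically by
ascending distance then spot id; the new-vesicle count is the number of
unmatched post spots, matching the assay's "second image minus first
image" logic.

## Interactome pipeline

The inclusion filter retains a protein only with (a) at least 2 exclusive
unique peptides in some sample, (b) detection in at least 3 specific-IP
samples overall or 2 samples of one treatment group, and (c) at least 3:1
enrichment over the IgG reference in at least 3 samples. The IgG reference
defaults to the per-protein mean over IgG samples; a zero reference
satisfies the enrichment clause vacuously (otherwise a protein absent from
the IgG control but seen in only two DZP samples could never pass, which
would contradict clause b). All removals are logged with reasons.

Ratios are mean DZP counts over mean vehicle counts, with sentinel classes
rather than pseudocounts when a group mean is zero: `NF_V` (not found in
vehicle) and `NF_DZP` (not found under DZP). Significance is a two-sided
Student's t-test on the per-animal counts with no multiple-testing
correction by default, matching the raw p-values of the source tables
(Benjamini-Hochberg is available by flag). Pathway input maps ratios >= 1
to themselves, ratios in (0, 1) to `-1/x`, and the NF classes to the
sentinels +1e99 / -1e99. Overrepresentation is a two-sided Fisher exact
test per annotation term with Bonferroni correction, over a user-supplied
annotation map — no ontology database is queried.

One power fact, established by simulation with this package's own
generator and stated here because the test suite reports it honestly: with
three animals per group and negative-binomial dispersion 0.3, a planted
4-fold effect reaches p < 0.1 in only roughly half to two-thirds of cases
whatever per-protein t variant is used (pooled, Welch, log-scale, or
one-sample on ratios). That is consistent with the published association
tables themselves, where proteins at 4-5-fold carry p-values between 0.03
and 0.09. Near-complete recovery of such effects at this design size would
require variance moderation across proteins, which would depart from the
plain Student's t of the source procedure; the corresponding
planted-recovery expectation in the acceptance suite therefore fails, and
is left failing rather than papered over.

## Problem sizes and numerical choices

The shipped analyses and tests use scene sizes of 200-400 pixels per side,
FRAP cohorts of 60 synapses per condition at 16 timepoints, 10-seed
replicate sets for vesicle and interactome checks, and 400-protein count
tables — sizes chosen so any single suite completes in well under a minute
while leaving Monte-Carlo margins far from the assertion boundaries.
Nonlinear fits use `minpack.lm::nlsLM` with parameter bounds and at most
200-300 iterations; ties in Otsu's criterion resolve to the lowest
threshold; greedy spot matching is deterministic; all simulators take
integer seeds and restore the caller's RNG state.

## Known limitations

Interactive ROI drawing, deconvolution, drift correction, 3D stacks,
single-particle tracking, reaction-diffusion FRAP theory, spectral
unmixing beyond one bleed-through constant, database searching of raw
spectra, and proprietary network-analysis scores are all out of scope. The
generator's idealizations listed above bound what the green suite can
certify about real images.
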