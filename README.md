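# synaptiq

Quantification pipelines for inhibitory-synapse receptor trafficking:
fluorescent puncta segmentation and synaptic colocalization, FRAP exchange
kinetics, intersubunit FRET with ordered restriction criteria, vesicle and
lysosome accumulation scoring, and a spectral-count co-immunoprecipitation
interactome filter. It is written for cell biologists and imaging
scientists studying how GABA-A receptors and the gephyrin scaffold
redistribute at inhibitory synapses — for example after benzodiazepine
exposure — and for anyone who needs those measurement procedures as
reproducible, tested code rather than interactive analysis.

All stages are exercised on synthetic scenes with recorded ground truth
(Gaussian-profile puncta, two-pool photobleach recovery, donor-quenching
FRET, vesicle fields, negative-binomial spectral counts), so the package
needs no external data to validate itself.

## The models at the core

**FRAP.** Each bleached synapse is normalized to percent of its first
post-bleach frame, `r(t) = I(t)/I(0) * 100`. Exchange kinetics follow the
two-pool model on the pre-bleach-fraction scale:

    g(t) = b + m (1 - b) (1 - e^{-k t})

with bleach depth `b`, mobile fraction `m`, and exchange rate `k` (1/min).
`fit_exchange_cohort()` fits conditions jointly with shared `m`, `b` (one
bleach protocol) and per-condition `k`, then re-fits `k` per synapse —
avoiding the k–m trade-off that skews independent per-trace fits over
short acquisition windows. Groups are compared by two-way ANOVA
(treatment × time) with Tukey HSD contrasts.

**FRET.** With transfer efficiency `E`, the donor emits `D(1 - E)`, the
FRET channel `A · E · c` (coupling `c ≤ 1`), the direct acceptor channel
`A`. Acceptor photobleaching restores the donor, so `E = 1 − pre/post`
donor intensity. Per-cell records pass four ordered restriction criteria
(≥15 synapses/cell; FRET:total ratio < 1; donor mean ≥ 500; donor sum ≤
300% of average), with per-criterion drop counts for audit.

**Interactome.** Proteins pass an inclusion filter (≥2 unique peptides;
detected in ≥3 samples overall or 2 of one group; ≥3:1 IgG enrichment in
≥3 samples), get DZP/vehicle count ratios with `NF-V`/`NF-DZP` sentinels
when a group mean is zero, Student's t p-values, pathway fold changes
(`x ≥ 1 → x`, `0 < x < 1 → −1/x`, sentinels ±1e99), and a generic
Fisher-exact overrepresentation test with Bonferroni correction.

## Worked example

Simulate two FRAP cohorts (vehicle-like `k = 0.02`/min vs accelerated
`k = 0.06`/min, 60 synapses each, 5% noise), recover the rates, and test
the treatment effect:

```r
library(synaptiq)

cohort <- function(k, stream)
  lapply(1:60, function(i)
    simulate_frap(kinetic_truth(k_exchange = k, mobile_fraction = 0.8,
                                bleach_depth = 0.2),
                  seq(0, 30, 2), pre_bleach = 100, noise_sd = 5,
                  seed = stream * 1000 + i, synapse_id = paste0(stream, "_", i)))
veh <- cohort(0.02, 1); dzp <- cohort(0.06, 2)

fit <- fit_exchange_cohort(list(vehicle = veh, dzp = dzp))
cmp <- compare_groups(list(vehicle = lapply(veh, normalize_trace),
                           dzp = lapply(dzp, normalize_trace)))
```

Running this via `analysis/03_frap.R` prints:

```
Shared fit: mobile fraction 0.780, bleach depth 0.200
vehicle  cohort k = 0.0206 /min; per-synapse median = 0.0210 /min (n = 60)
dzp      cohort k = 0.0635 /min; per-synapse median = 0.0637 /min (n = 60)
Tukey treatment contrast: diff -97.4%, adjusted p = 2.39e-11
Timepoints with adjusted p < 0.05: 14 of 15
```

The planted rates (0.02 and 0.06/min) and mobile fraction (0.8) are
recovered; the treatment effect — a tripled synaptic exchange rate — is
detected decisively, and the per-timepoint Tukey contrasts localize it to
every post-bleach timepoint but the earliest. The classification side works
the same way: `classify_association(as_association_records())` on the
packaged association table yields 46 proteins with increased association
(10 found only under DZP) and 23 decreased (7 found only in vehicle), and
`to_pathway_input()` maps, e.g., ratio 0.2 to −5.0.

The numbered scripts under `analysis/` walk through every stage
(simulation, puncta, FRAP, FRET, vesicles, interactome) and write their
tables under `results/`.

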