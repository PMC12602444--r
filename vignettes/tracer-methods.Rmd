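---
title: "Quantifying interplant resource transfer from dual 13C/15N labelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interplant resource transfer from dual 13C/15N labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotrace)
```

## The problem

Plants that share a mycorrhizal fungus can exchange resources through the
hyphal network that links their roots. A dual stable-isotope labelling
experiment quantifies this exchange: one plant in a microcosm is exposed to
^13^CO~2~ while its partner receives a foliar ^15^N solution, the microcosm
is harvested after a labelling window, and isotope-ratio mass spectrometry
(IRMS) measures each tissue's ^13^C/^12^C and ^15^N/^14^N composition,
carbon and nitrogen contents, and dry biomass. Unlabelled reference
microcosms provide the natural-abundance baseline. The analysis must turn
these measurements into directional tracer fluxes — how many micrograms of
carbon and nitrogen moved from each plant to its partner, what fraction of
the donor's uptake that represents, and whether the exchange is
unidirectional, bidirectional, and with or without a net flux.

`mycotrace` implements that analysis as a tested pipeline, together with a
synthetic microcosm-experiment generator with known ground truth so every
stage can be verified end to end without access to any particular
laboratory's raw data.

## The mass-balance model

**Units.** Internally every isotope composition is an *atom fraction* — the
proportion of the element's atoms that are the heavy isotope, a
dimensionless number in [0, 1]. Delta notation (per mil against VPDB for
carbon, atmospheric N~2~ for nitrogen; reference ratios 0.0111802 and
0.0036765) and atom percent exist only at input/output boundaries. This
matters because the micrograms-from-grams factor of 10^6^ in the mass
balance is only dimensionally coherent when enrichment and element content
are proper fractions; mixing percent and fraction notation is the classic
failure mode of these calculations, so the conversion happens exactly once,
at ingest.

**Enrichment.** For each labelled plant tissue the atom-percent excess
(APE) is the measured atom fraction minus the control baseline for the same
species, tissue and element, with controls pooled across all unlabelled
microcosms. Negative excess — possible whenever a labelled measurement
falls below the baseline through instrument noise — is retained and
flagged, never clipped: clipping would bias replicate means upward.
Detection (below) decides significance.

**Pools.** Tracer mass in a tissue is

$$m \;[\mu g] = \mathrm{APE} \times w \times B \times 10^{6}$$

with $w$ the element mass fraction (C% or N% / 100) and $B$ the tissue dry
biomass in grams. Whole-plant pools are sums of tissue masses — the only
conservation-respecting aggregation; averaging atom percents across tissues
is not mass-weighted and is deliberately not offered. For each labelled
microcosm and element this yields a donor pool (tracer assimilated by the
labelled plant: ^13^C fixed from ^13^CO~2~, or ^15^N taken up through the
soaked leaves) and a recipient pool (tracer recovered in the partner plant,
which can only have arrived through the fungal connection).

**Percent transferred.** The headline statistic for a direction is

$$P_{TR} = 100 \times \frac{\text{transferred}}{\text{transferred} + \text{assimilated}}$$

the share of the donor's total uptake that ended up in the partner. It is
bounded in [0, 100] and, in the generator's terms, equals $100\,\varphi$
where $\varphi$ is the transferred fraction — so simulated experiments have
an exact ground truth for it. Percent values are summarized across
replicate microcosms as mean ± standard error.

## Detection

A recipient pool only demonstrates transfer when its enrichment exceeds
what noise alone produces. The threshold for a plant's biomass-weighted
mean excess is

$$T = \max\bigl(2\,\sigma_{analytical},\; 2\,\sigma_{control}\bigr)$$

both expressed in atom fraction: $\sigma_{analytical}$ is the quoted IRMS
precision (default 0.15 per mil, the instrument-repeatability figure
typical of continuous-flow IRMS) converted at the control operating
composition, and $\sigma_{control}$ is the observed dispersion of the
control measurements, combined across tissues with the same biomass
weights. Detection requires strict exceedance; a value exactly at the
threshold is not detected. A recipient pool that fails detection is
reported as 0 µg with flag `below_detection` (its raw value is kept in a
separate column), and a *direction* counts as detected when more than half
of its replicate microcosms detect — a majority rule that makes the
direction-level false-positive rate negligible when the per-microcosm rate
is at the ~2 σ level.

## Net transfer and pattern classification

The two directions of one element are measured in different microcosms
(the reciprocal labelling orientations), so the net flux is a two-sample
difference of means with, typically, four replicates per side. The
interval is a seeded percentile bootstrap, resampling each direction's
microcosms independently. At $n = 4$ the raw percentile interval is
systematically narrow — its spread uses $1/n$ variances and normal rather
than t quantiles — so the quantile levels are expanded in the style of
Hesterberg's expanded-percentile interval, using the conservative
$\min(n_1, n_2) - 1$ degrees of freedom (a Welch estimate of the degrees of
freedom is itself too noisy at these sizes to be worth its width savings).
Monte-Carlo checks during development put the raw percentile interval near
86% coverage and the expanded, conservative-df interval near 97–98% at the
default study conditions; the conservative choice protects the claim that
carries the most scientific weight here, namely declaring a *net*
direction. The interval construction is exactly antisymmetric: swapping
the two directions negates the estimate and mirrors the interval draw for
draw under the same seed.

Patterns follow from the detection verdicts and the interval:

| both detected | interval vs 0 | pattern |
|---|---|---|
| neither | — | `none` |
| exactly one | — | `unidirectional` (toward the detected side) |
| both | spans 0 | `bidirectional_no_net` |
| both | excludes 0 | `bidirectional_net` (direction from the sign) |

"No net transfer" is therefore operationalized as *the 95% interval for
the net flux includes zero* — a deliberate choice, since qualitative
descriptions like "almost no net transfer" have no unique statistical
reading.

## Group comparisons

`compare_groups()` packages the conventional battery for comparing
treatment means: Shapiro–Wilk on the ANOVA residuals, Levene's test
(mean-centered, the classical form) for variance homogeneity, one-way
ANOVA, and Tukey's HSD at α = 0.05 with a compact letter display
(`multcomp::cld`). Pre-check failures warn rather than stop: with four
replicates per group the pre-tests have little power in either direction,
and the analyst should see the ANOVA either way.

## The synthetic experiment generator

`simulate_experiment()` draws complete microcosm experiments from an
explicit generative model:

1. Two labelling orientations are always generated (`n_labelled` microcosms
   each, default 4, plus `n_control` controls, default 4), mirroring the
   reciprocal design.
2. Per labelled microcosm and element, the donor's tracer uptake $T$ is
   lognormal (default CV 0.3 — uptake is multiplicative and positive); a
   fraction $\varphi$ of $T$ moves to the partner, $1-\varphi$ stays.
3. Retained tracer is split 70/30 aboveground/belowground in the donor;
   received tracer 40/60 in the recipient (root-biased retention, but some
   tracer demonstrably reaches the partner's shoot). Both are configurable.
4. Tissue tracer mass becomes an atom-fraction increment through the
   tissue's element pool (biomass × content, biomass lognormal with CV
   0.2), is added to the natural-abundance baseline (δ^13^C = −27 ‰,
   typical C3 tissue; δ^15^N = 0 ‰), and Gaussian measurement noise of sd
   0.15 ‰ is added *in per-mil space* — the space in which IRMS precision
   is quoted; applying it in atom-fraction space would misscale the two
   elements relative to each other.
5. Controls are baseline + noise only. Everything is deterministic under a
   fixed seed, and tracer is conserved exactly before noise.

**Parameter choices.** Transfer fractions in the three named scenarios
(`transfer_scenarios()`) use percent-transferred values in the range
dual-labelling studies of orchid–pine systems report (carbon 1.4–3.0%,
nitrogen 0.25–9.0%), divided by 100. Uptake magnitudes have no
off-the-shelf values, so they were chosen once from the biology and
frozen: a pine seedling
photosynthesizes far more than a mixotrophic understory orchid (12 000 vs
1 000 µg ^13^C at default), while orchids are the nitrogen-richer partner
(400 vs 300 µg ^15^N). These magnitudes are what make "2.7% of the
orchid's carbon" a smaller absolute flux than "1.4% of the pine's carbon",
reproducing the universal net carbon flow toward the orchid. Element
contents (orchid ~45% C, ~2% N; pine ~48–50% C, ~1–1.2% N) and biomasses
(orchid 1.2 g, pine 2.5 g total) are in the ranges typical of such
seedlings.

**What the generator does not emulate.** Real data add fungal-biomass
retention of tracer, time-resolved uptake kinetics, isotope fractionation
during transfer, spatial heterogeneity within tissues, and
non-Gaussian instrument drift. Passing tests on synthetic data therefore
demonstrate that the *arithmetic and inference chain* is correct and
well-calibrated under the stated error model — not that any particular
field estimate is accurate. That caveat is inherent to every tracer mass
balance of this design, not to this implementation.

## Numerical choices and degenerate inputs

* Conversions are closed-form and round-trip to < 10^−9^ ‰ across
  −1000–10 000 ‰; a delta below −1000 ‰ or an atom fraction ≥ 1 is a hard
  error (they imply negative ratios or division by zero).
* `percent_transferred(0, 0)` is undefined and errors; negative transferred
  masses are floored to zero in the ratio only.
* Detection at exactly the threshold is *not* detected (strict
  inequality, documented tie-break).
* With a single replicate in a direction the net interval is flagged
  `ci_unavailable` rather than fabricated.
* The bootstrap expansion falls back to raw percentile levels when a
  direction has zero variance.
* Problem sizes in the test suite — 500 simulated experiments for
  parameter recovery and per-scenario classification, 1000 for null
  calibration — give Monte-Carlo standard errors comfortably below the
  margins they check.

## A worked run

```{r example, eval = FALSE}
cfg <- transfer_scenarios()[["serratum-like"]]
sim <- simulate_experiment(cfg, seed = 1)
res <- quantify_transfer(sim$measurements, seed = 1)
res$transfers[, c("element", "donor_role", "percent", "percent_se")]
print(res)   # text report with arrows, net interval and pattern call
```

The same stages are scriptable from a shell through the thin command-line
wrapper installed under `exec/mycotrace`
(`simulate`/`quantify`/`report` subcommands; exit codes 0 = ok, 1 =
empty/degenerate input, 2 = configuration or schema error).

## Known limitations

* Controls are pooled per species × tissue; there is no per-microcosm
  control pairing (none is identifiable from the design).
* The recipient-pool detection rule assumes control scatter is
  representative of labelled-microcosm scatter at baseline.
* The net-transfer interval is conservative by construction at n = 4;
  with many replicates its extra width over a raw percentile interval
  vanishes, but for n < 3 per direction no interval is attempted.
* No fungal compartment: tracer resident in the shared mycelium at
  harvest is invisible to a plant-endpoint mass balance and is not
  modelled.
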