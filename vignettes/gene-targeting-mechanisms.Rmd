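---
title: "Mechanistic models of gene targeting and their marker-retention signatures"
author: "GeneTargeting authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic models of gene targeting and their marker-retention signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneTargeting)
```

## The experimental system being modelled

Gene targeting replaces a chromosomal segment with a selection cassette
flanked by two homology arms. When the vector carries polymorphic markers on
its arms — restriction-site SNPs and small hairpin palindromes — each
recovered clone reports, marker by marker, how much of each arm was
physically incorporated. Across a panel of clones, the per-marker *retention
frequency* plotted against the marker's distance from the central heterology
(the cassette junction) is a mechanistic fingerprint: each candidate
recombination mechanism predicts a different retention curve, a different
mitotic-sectoring behaviour, and a different response to drug selection.

`GeneTargeting` implements those mechanisms as forward simulators over an
abstract locus geometry (a `MarkerMap`), emits per-clone genotype tables
(`CloneTable`, an extension of `SummarizedExperiment`: markers as rows,
clones as columns, one call `V`/`C`/`S`/`N` per cell), and provides the
statistics that discriminate the mechanisms. No nucleotide-level sequence is
represented anywhere: the locus is a geometry of marker positions, which is
exactly the resolution of the underlying assay.

The default fixture map mirrors the marked *HPRT* targeting system: 1 kb
homology arms, four restriction-site SNPs plus one hairpin per arm
(left arm, inner to outer: AseI 300, NcoI 547, LHP 650, EcoRI 800, NdeI 950;
right arm: SspI 130, SacI 261, RHP 400, XbaI 600, SbfI 800). NcoI (−547) and
SacI (+261) sit at their literature positions, as do the two meganuclease
knock-in positions used for DSB-induced targeting (−569 and +266); the
remaining distances are fixture values consistent with the published marker
ordering, and everything is configurable through `MarkerMap()` or the
text-config reader. True arm lengths and exact positions of the other
markers are not recoverable from the published material, which is why they
are explicit parameters rather than constants.

## The mechanisms and their predictions

### Ends-out double-HJ resolution (spontaneous targeting)

The vector invades the intact chromosome in an ends-out configuration,
producing a double-Holliday-junction intermediate. The package's central
modelling commitment is that **resolution positions are uniformly
distributed over each homology arm**. For a marker at distance $d$ on an arm
of length $L$, the probability that a uniformly placed crossover falls
beyond the marker — retaining it — is

$$P(\text{retain}) = 1 - d/L,$$

a straight line in $d$. This is the model a linear retention gradient
supports; the classical alternative, crossovers concentrated near the
initiation site by branch migration, yields an approximately exponential
curve $A e^{-kd}$. Both are fitted by `fitRetentionModel()` and compared by
residual sum of squares in `compareRetentionModels()`, with R² computed as
$1 - RSS/TSS$ about the mean for both models so the two are on the same
scale. No branch-migration term is included in the default simulator:
human Rad51's branch-migration activity is weak, and the linear signature
is the observation the model family is anchored to.

Two sampling modes correspond to the two assay designs:

* **SEGREGANT** — the clone is picked after the heteroduplex has segregated
  at mitosis. Per arm, the retained strand's crossover is a single
  $U(0, L)$ draw (drawing two strand positions and choosing one at random
  is distributionally identical, so the simulator draws once).
* **COLONY** — the colony grows in situ and contains both daughter
  genotypes. Two strand crossovers $x_1, x_2 \sim U(0, L)$ per arm give a
  three-zone call: `V` inside both tracts, `S` (sectored) between them, `C`
  beyond both. The two daughter genotypes are retained as `subcloneA`/
  `subcloneB` assays, with strand bookkeeping such that a single event
  always segregates the two arms in *trans*: the daughter inheriting the
  longer viral tract on the left arm inherits the shorter one on the right.

### Single-strand assimilation

A single viral strand anneals into chromosomal heteroduplex. The daughter
cell without the cassette dies under selection, so the surviving colony is
homogeneous: identical marginal retention law ($1 - d/L$, one crossover per
arm) but **zero sectored calls**. The sectored fraction of a colony panel
therefore separates the two models even though their retention curves are
indistinguishable — and `simulateSSA()` versus segregant-mode
`simulateEndsOut()` are statistically indistinguishable by design, which the
test suite checks with per-marker two-proportion tests.

### The double-event mixture and the trans/cis estimator

A sectored colony could also arise from two independent targeting events in
one colony. A single heteroduplex event is always *trans*; two independent
events are *trans* or *cis* with equal probability. A mixture with
double-event fraction $q$ therefore shows a trans proportion
$p = 1 - q/2$ among both-arm-sectored colonies, inverted by
`estimateDoubleEventFraction()` as $q = 2(1 - p)$ (the observed 89.6% trans
maps to $q = 0.208$). `simulateDoubleEventMixture()` implements the mixture
generatively: double-event colonies are assembled from two independent
segregant genotypes, so their arm orientation is uniform without any
explicit coin flip. Configuration calls (`classifyConfiguration()`) demand
reciprocal subclones at every parent-sectored marker and an arm-consistent
viral carrier; any violation — one-arm sectoring, non-reciprocity,
within-arm disagreement (possible only with injected genotyping noise) —
returns `AMBIGUOUS` rather than a forced call.

### DSB-induced ends-in targeting

With a chromosomal DSB at position $s$ on one arm, the broken chromosome
ends invade the vector (ends-in). Two resolution routes are modelled, mixed
by `pAlt`:

* **DSBR** — distal junction $y \sim U(s, L)$ on the DSB arm; proximal
  junction at a signed position uniform over cassette-plus-far-arm. Drug
  selection keeps only events whose conversion tract covers the cassette,
  which (i) forces retention of *every* marker between cassette and DSB —
  the plateau is exact, not statistical — and (ii) leaves distal markers
  retained with probability $(L-d)/(L-s)$ and far-arm markers with
  probability $1 - d/L_{\text{other}}$.
* **ALT (SDSA / HJ dissolution)** — merged into one pathway because they
  predict identical marker signatures: retention of one half of the
  meganuclease recognition site (`halfSitePresent`), the full plateau up to
  $s$, and loss of everything distal.

Two modelling decisions deserve emphasis. First, the cassette is a
geometric point: no cassette length is published, so proximal resolution
"inside" the cassette is not representable — events either cover it or are
rejected by selection. Second, `pAlt` is defined as the pathway fraction
**among surviving clones**. If a selection-rejected DSBR event were redrawn
from scratch (pathway included), survivors would be ALT-enriched relative to
the nominal mixing weight; defining the mixture on survivors keeps `pAlt`
interpretable as the fraction a genotyping experiment would observe, which
is how the 17% minor-pathway figure is quoted. Selection rejection of DSBR
events still feeds the `attempts()` counter.

`classifyPathway()` uses the half-site flag as the sole discriminator —
a DSBR clone whose distal junction lands before the first distal marker is
pattern-identical to ALT except for the half site — and flags the
impossible combination (half site plus a retained distal marker) as
`INCONSISTENT`, a useful sentinel for genotyping noise.

### Random integration

Integration through the vector termini leaves the homology arms intact:
every marker `V` in every clone, slope exactly zero. This is the null
signature that distinguishes targeted from random integrants.

### Mismatch-repair anti-recombination

Mismatch repair rejects mismatched heteroduplex intermediates. The model is
**event-level** rejection: an event with $m$ vector mismatches survives with
probability $(1-r)^m$, independent of where the junctions landed. This
choice is deliberate: the retention profile is observed to be unchanged in
MMR-proficient cells, ruling out tract-length-dependent rejection as the
default (a per-event model changes efficiency, never geometry — a property
the test suite verifies by comparing profiles at $r = 0$ and $r = 0.3$).
`calibrateRejection()` inverts an observed efficiency fold-change between
two vectors: $r = 1 - \rho^{-1/(m_l - m_s)}$, giving $r \approx 0.144$ for
the 7.5-fold effect between 2- and 15-mismatch vectors. Host proficiency is
a single multiplicative factor `hostSuppression` (default 50, the printed
lower bound of the MLH1⁺ effect) rather than a second per-mismatch term: a
per-mismatch host model cannot produce the same ≥50-fold suppression for
both a 2- and a 15-mismatch vector simultaneously. A per-mismatch
alternative remains available by calibrating a separate `rReject` for the
proficient host. Spell-checking (tract patching, to which hairpin markers
would be refractory) is deliberately **not** part of the default model:
no spell-checker signature is observed in the data the model targets.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `nClones` | accepted clones per table | 100 | panels of 10–250 match the emulated experiments; acceptance tests use the published 230/38/5000 |
| arm lengths | homology per arm (bp) | 1000/1000 | accommodates the outermost fixture marker; true lengths unpublished |
| `pAlt` | SDSA/dissolution fraction among survivors | 0.17 | the observed minor-pathway fraction |
| `dsb` | break arm/position (bp) | none | +266 / −569 are the meganuclease knock-in positions |
| `rReject` | per-mismatch rejection probability | 0 | calibrate with `calibrateRejection()`; 0.144 reproduces the 7.5-fold vector effect |
| `hostSuppression` | MMR-proficient penalty | 50 | printed lower bound, taken as stated |
| `nMismatches` | vector mismatch count $m$ | 15 | the fully marked vector; 2 for the low-mismatch variant |
| `errorRate`, `missingRate` | genotyping noise | 0 | noise is post-hoc (`addNoise()`), never inside the mechanism models, keeping the mechanistic oracles exact |

## Numerical choices and degenerate inputs

* Crossover positions are continuous $U(0,L)$ draws against integer marker
  distances, so call ties have probability zero; the boundary convention is
  `V` strictly inside, `S` at the closed sectored interval.
* Rejection sampling is implemented as a negative-binomial draw for the
  attempt count plus direct simulation of accepted-event geometry — exact in
  distribution because rejection is independent of geometry, and O(n)
  regardless of acceptance rate.
* The linear fit is plain OLS of frequency on unsigned distance, per arm,
  hairpins included as ordinary points (they follow the same regression);
  an inverse-variance weighted fit is available but off by default, matching
  standard practice for these retention plots. Sectored markers count as
  retained by default (`countSectoredAsRetained`), since a sectored colony
  demonstrably carries the viral allele; the flag exists because either
  counting convention is defensible.
* The exponential fit is Levenberg–Marquardt (`minpack.lm::nlsLM`) started
  from a log-linear fit on the positive frequencies; an all-zero profile is
  an error, and a profile with zero variance defines R² as 1 when the
  residuals are also zero (otherwise 0) so R² stays in $[0,1]$.
* Model comparison prefers the lower RSS with ties broken to linear.
* `fitRetentionModel()` requires ≥3 informative markers per arm; markers
  with only no-calls are excluded marker-wise, not clone-wise.

## What the synthetic data does and does not establish

Every table in the test suite is generated by the mechanism models
themselves, so the statistical suite demonstrates *internal* consistency:
the estimators recover the generators' parameters (closed-form retention
laws at $n = 10^5$ within binomial 3σ, `pAlt` recovery at $n = 5000$,
double-event fraction round trips, exact pathway separation on noise-free
tables, ≥18/20 correct linear-vs-exponential model selections at the
published panel size of 230). What passing these tests does **not** show is
that real clones obey the generative assumptions — uniform resolution,
independent per-arm junctions, event-level MMR rejection, a point cassette.
Those assumptions are exactly what the retention statistics are designed to
interrogate on real genotype tables, which enter through
`readCloneTable()`. The noise injector emulates genotyping error and
missingness only; it does not emulate discontinuous conversion tracts,
doublet colonies beyond the double-event mixture, or partial restriction
digestion.

Problem sizes used by the checked examples — 230-clone retention panels
(100 seeds), 1000-clone ends-in panels, 38 random integrants, $10^5$
Monte-Carlo events per MMR condition, 5000-colony mixtures — mirror the
emulated experiments where a published size exists and otherwise are chosen
to hold the Monte-Carlo error well inside the quoted tolerances.

## A worked example

```{r example}
map <- makeDefaultMap()
tab <- simulateEndsOut(map, SimParams(nClones = 230, seed = 1))
prof <- retentionProfile(tab)
fitRetentionModel(prof, "LEFT", "LINEAR")
fitRetentionModel(prof, "RIGHT", "LINEAR")
compareRetentionModels(prof, "LEFT")$preferred
```

```{r sectoring}
col <- simulateDoubleEventMixture(map, SimParams(nClones = 1000, seed = 2),
                                  q = estimateDoubleEventFraction(0.896))
s <- sectoringSummary(col)
c(sectored = s$sectoredFraction, pTrans = s$pTrans)
```

```{r mmr}
r <- calibrateRejection(7.5, 15, 2)
mmr <- SimParams(rReject = r)
relativeEfficiency(mmr, 2) / relativeEfficiency(mmr, 15)
```

## Known limitations

* No nucleotide-level chemistry: strand polarity exists only as the trans
  bookkeeping needed for configuration calls, and restriction digestion or
  sequencing are abstracted into oracle calls.
* The joint law of the two junctions per arm is taken as i.i.d. uniform;
  the published data constrain the marginal, not the joint, distribution.
  A fixed-tract alternative would change sectored-tract length statistics
  but not the retention curve.
* Absolute targeting frequencies (events per cell) are outside the model:
  all efficiencies are relative, which is why the meganuclease
  fold-enhancement of targeting is not a model output.
* One `rReject` serves an MMR-"deficient" host even though residual
  mismatch-repair activity differs between deficient lines; the calibration
  data cannot separate them.
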