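# GeneTargeting

Mechanistic simulation and marker-retention analysis of gene targeting in
human somatic cells.

## The problem

When a targeting vector — a drug-selection cassette flanked by two homology
arms carrying polymorphic markers (restriction-site SNPs, hairpin
palindromes) — integrates at its chromosomal locus, the per-clone genotype
at each marker records how much of each arm was incorporated. Different
recombination mechanisms leave different fingerprints in a panel of clones:

* **Ends-out double-HJ resolution** with uniformly distributed junction
  positions predicts marker retention falling *linearly* with distance
  `d` from the central heterology: `P(retain) = 1 − d/L` on an arm of
  length `L`, and mitotically *sectored* colonies whose subclones segregate
  the two arms in **trans**.
* **Single-strand assimilation** predicts the same retention line but zero
  sectored colonies (the cassette-free daughter dies under selection).
* **DSB-induced ends-in targeting** (broken chromosome invades the vector)
  predicts, after selection, an exact 100% retention plateau between the
  cassette and the break at `s`, and `(L − d)/(L − s)` beyond it; its
  SDSA/HJ-dissolution variant additionally retains half of the meganuclease
  site and loses all distal markers.
* **Random integration** keeps the arms intact: 100% retention everywhere.
* **Mismatch-repair anti-recombination** rejects each event with
  probability `1 − (1 − r)^m` for a vector with `m` mismatches, changing
  efficiency but never tract geometry; a proficient host adds a
  multiplicative suppression factor (default 50).

The package implements these mechanisms as forward simulators over an
abstract locus geometry (`MarkerMap`), stores per-clone calls
(`V`/`C`/`S`/`N`) in a `CloneTable` extending `SummarizedExperiment`, and
provides the discriminating statistics: retention profiles with
linear-vs-exponential model fits, sectoring and trans/cis configuration
analysis with a double-event mixture estimator (`q = 2(1 − p_trans)`),
per-clone pathway classification, and mismatch-repair calibration
(`r = 1 − ρ^{−1/(m_l − m_s)}`). Intended users are researchers modelling
gene-targeting or gene-editing outcomes and anyone analysing marker-panel
genotype tables from targeting experiments.

## Worked example

```r
library(GeneTargeting)

map <- makeDefaultMap()                       # 10-marker, 1 kb/1 kb fixture
tab <- simulateEndsOut(map, SimParams(nClones = 230, seed = 1))
prof <- retentionProfile(tab)
prof[, c("id", "signedDistance", "freq")]
#>     id signedDistance       freq
#>   NdeI           -950 0.03913043
#>  EcoRI           -800 0.18260870
#>    LHP           -650 0.34782609
#>   NcoI           -547 0.45652174
#>   AseI           -300 0.73043478
#>   SspI            130 0.87826087
#>   SacI            261 0.72608696
#>    RHP            400 0.55652174
#>   XbaI            600 0.35652174
#>   SbfI            800 0.19565217

fitRetentionModel(prof, "LEFT", "LINEAR")
#> LINEAR retention fit, LEFT arm (5 markers)
#>   slope = -0.00106874, intercept = 1.04534
#>   R^2 = 0.9993, RSS = 0.0002011
```

Retention falls from ~0.88 at the innermost marker to ~0.04 at the
outermost, and the per-arm least-squares line fits with R² ≈ 0.99: the
linear gradient expected when junction resolution is uniform over the arm
(slope ≈ −1/L = −0.001 per bp, intercept ≈ 1).

```r
q <- estimateDoubleEventFraction(0.896)       # 0.208
col <- simulateDoubleEventMixture(map, SimParams(nClones = 1000, seed = 2), q)
s <- sectoringSummary(col)
c(sectored = s$sectoredFraction, pTrans = s$pTrans)
#> sectored   pTrans
#>   0.9660   0.8815
```

96.6% of simulated colonies are sectored on at least one arm, and among
both-arm-sectored colonies 88.2% of subclone pairs classify as trans —
consistent with the mixture arithmetic `p_trans = 1 − q/2` at the
double-event fraction `q = 0.208` implied by an observed 89.6% trans
proportion.

```r
calibrateRejection(7.5, 15, 2)
#> [1] 0.1435784
```

A 7.5-fold efficiency difference between 2- and 15-mismatch vectors
calibrates a per-mismatch rejection probability of ~0.144.

A command-line wrapper (`inst/scripts/genetargeting`) exposes `simulate`,
`analyze-retention`, `analyze-sectoring`, `classify-pathway`,
`calibrate-mmr` and `report` subcommands over TSV tables; see `?runCLI`.
The methods vignette (`vignettes/gene-targeting-mechanisms.Rmd`) documents
the models, assumptions and numerical choices.

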