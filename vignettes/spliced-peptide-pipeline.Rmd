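---
title: "Identifying and quantifying proteasome-generated spliced peptides"
author: "ProteoSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying proteasome-generated spliced peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoSplice)
```

## The scientific problem

Proteasomes degrade polypeptides by hydrolysis, but they can also ligate
two non-contiguous fragments of a substrate into a *cis*-spliced peptide
(proteasome-catalysed peptide splicing, PCPS). Spliced products are not
encoded in the genome, so identifying them from in vitro digestions of a
synthetic substrate requires (i) enumerating every sequence the substrate
could theoretically yield, (ii) matching MS2 fragment spectra against that
candidate space under strict score filters, and (iii) quantifying product
formation over digestion time by extracted ion chromatograms (XICs).

The model system throughout is the KRAS 2-35 G12V substrate
`TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT` and its isobaric product pair:

* `KLVVGAVGV` — *cis*-spliced, splice reactants KL (residues 5-6) and
  VVGAVGV (8-14), skipping V7;
* `KLVVVGAVG` — non-spliced, residues 5-13.

Both have neutral monoisotopic mass 840.54329 Da (identical residue
multisets), so their doubly protonated precursors are indistinguishable at
m/z 421.27892. Discriminating them relies on diagnostic fragment ions —
the b/y fragments whose residue composition differs — and on distinct
chromatographic retention times measured on synthetic standards.

```{r isobars}
neutralMass("KLVVGAVGV") - neutralMass("KLVVVGAVG")
precursorMz("KLVVGAVGV", 2)   # inside the XIC window 421.275-421.875
```

## Candidate peptidome enumeration

`enumerateNonspliced()` lists every substring within the configured length
bounds; `enumerateCisSpliced()` lists every ligation of two reactants cut
from one molecule. Normal-order events require at least one skipped
residue (a zero gap is simply the non-spliced case); reverse-order events
require non-overlapping reactants, adjacency allowed, because one molecule
cannot contribute a residue twice. Products are deduplicated by exact
sequence, and every generating origin is retained in protein coordinates
(`"5-13"`, `"5-6/8-14"`).

Defaults that the data do not dictate, declared once:

* **Length bounds 5-25 residues.** The window brackets HLA class I
  relevant lengths and keeps the enumeration desk-scale; configurable.
* **Reverse cis is enumerated by default**, trans-splicing (reactants from
  two molecules) is out of scope.
* Modified peptidoforms (M oxidation +15.994915 Da, N/Q deamidation
  +0.984016 Da, up to `maxVariableMods` sites) are expanded after
  sequence-level deduplication.

The enumeration is verified in the test suite against an independent
brute-force double loop over all interval pairs, both at the event level
and on deduplicated sequence sets.

## Fragment arithmetic and MS2 annotation

`theoreticalFragments()` generates b, a (= b − CO) and y ions at indices
1..n−1, with ammonia-loss variants (−17.026549 Da) and charge states up to
2 by default (water loss is available behind a flag but off by default, as
only ammonia loss is routinely annotated in these spectra). The residue
mass table is data, pinned to six decimals, so tests can assert exact
values. Structural invariants — b/y complementarity, the a/b offset, the
charge-2 relation, and modification locality — are property-tested over
random peptides.

`annotateSpectrum()` assigns each theoretical ion the nearest unused peak
within tolerance, processing ions in ascending m/z; the assignment is
deterministic and each peak is used at most once. Tolerances mirror the
instrument presets used for such measurements: 20 ppm (`"QE-HF"`) or
0.02 Da (`"Exploris"`).

For isobaric candidates, `diagnosticIons()` partitions each candidate's
ions into mass-shared and diagnostic sets by pairwise tolerance
comparison; for the KRAS pair (b/y, singly charged) the diagnostic set is
{b5, b6, b8, y1, y3, y4} and the shared set
{b1-b4, b7, y2, y5-y8}, exactly the fragments whose residue composition
differs. `supportInSpectrum()` counts observed diagnostic peaks per
candidate; the verdict requires strictly more support, with ties declared
ambiguous.

`matchScore()` is a documented surrogate for a proprietary search-engine
ion score: −10·log10 of the binomial tail probability of matching at least
k of m theoretical ions given a per-ion random-match probability
(peak count × window width / spectrum span). The filter treats scores as
an opaque column, so externally computed scores can be imported instead.

## The identification filter

`filterHits()` applies, per MS2 scan: only the unique top-scoring hit can
be accepted (ties reject the scan); ion score ≥ 20 and q-value ≤ 0.05
(inclusive cutoffs); and for a spliced top hit two relative score-gap
conditions, Δ = 100·(S_top − S_other)/S_top, of at least 10% against the
best other spliced hit and at least 30% against the best non-spliced hit.
A missing competitor satisfies its condition vacuously; scans whose top
score is non-positive are rejected outright because the percentage gap is
undefined. The two delta conditions combine with AND by default — the
stricter reading, since the source protocol states them jointly without an
explicit connective — and `deltaCombine = "or"` is available. The filter
is validated against a generator (`simulateHitTable()`) whose acceptance
outcome is computed at generation time by direct arithmetic on the drawn
score gaps.

## XIC quantification

`extractXic()` sums per-scan intensity inside an inclusive m/z window
(the KRAS pair uses 421.275-421.875). `detectPeak()` takes the highest
local maximum within `rtTol` (default 0.5 min) of the reference RT — the
apex measured on the cognate synthetic standard — and calls presence by
signal-to-noise. Numerical choices:

* **Integration bounds at 5% of apex intensity**, extended by linear
  interpolation to the exact threshold crossings; with a zero baseline and
  trapezoidal integration this recovers ~98.6% of a Gaussian peak (the
  analytic mass within ±2.45σ), i.e. a relative error of ~1.4%,
  within the 2% recovery the quantification tests assert.
* **SNR = apex / median of the trace outside the bounds**, floored at
  machine epsilon, with presence requiring SNR ≥ 3. A median background is
  robust to the peak itself but degenerates to zero on sparse traces, so a
  peak must additionally span **at least 3 scans** above the bound
  threshold — an isolated one-scan spike is noise, not chromatography.
* Technical replicates are combined by the mean; biological replicates are
  reported separately (`kineticsSeries()`).

## What the simulators emulate — and what they do not

The generators are pure functions of (configuration, seed) and emulate the
structure of the underlying kinetics experiments: 3 biological × 5 time
points (0-4 h) × 3 technical replicate runs (45 kinetics runs), 0 h and
no-proteasome negative controls, and synthetic-standard reference runs
with known RTs.

* **Digestion:** biphasic first-order substrate decay
  S(t) = exp(−k1·min(t,τ) − k2·max(0, t−τ)), with product amounts tied to
  consumption, P_i(t) = α_i·(1 − S(t)). The first-phase rate defaults to
  k1 = ln(4)/4 ≈ 0.3466 h⁻¹ with τ = 4 h, so that a quarter of the
  substrate remains at 4 h; k2 = 0.2 h⁻¹ makes a 20 h endpoint
  near-complete (~1% remaining). This is the simplest mass-balance-
  flavoured form — no cleavage-site preference or splicing-propensity
  model is attempted.
* **MS2 spectra:** per-ion Bernoulli detection, Gaussian ppm jitter,
  log-normal intensities, uniform noise peaks.
* **Chromatograms:** Gaussian elution (σ = 0.1 min) on a 0.02 min scan
  grid, small per-run RT drift (σ = 0.03 min), and a continuous shallow
  noise baseline (intensities uniform in [noiseLevel/2, noiseLevel] at m/z
  across the window) — like a real blank XIC, and deliberately not a
  sparse-spike background, which would make a median-based SNR
  meaningless.
* The default scenario (`krasScenario()`) plants the product pair at
  reference RTs 10 and 12 min — RT-resolved, as observed on the real
  standards; a `"co_eluting"` stress configuration (gap 0.2 min) is
  provided.

Passing tests on these simulations show that each stage implements its
contract and that the chain recovers planted ground truth; they do not
show robustness to real-data features the simulators omit: profile-mode
peak shapes, isotope envelopes, co-eluting interferences, chimeric MS2
spectra, intensity-dependent mass error, or chromatographic tailing.

## End-to-end reproduction of the qualitative result pattern

`runSplicePipeline()` chains the stages on a simulated bundle: reference
RTs from the standard runs, RT resolution, per-peptide kinetics, control
presence calls, and MS2 identity confirmation (surrogate score ≥ 20 plus a
correct diagnostic-ion verdict). On the default scenario both planted
products are identified at 2-4 h, neither at 0 h nor in no-proteasome
controls, and the references are RT-resolved — the qualitative pattern the
pipeline is designed to detect. The problem sizes used in tests (full
3×5×3 bundle, 10,000 simulated filter scans, 100-seed Monte Carlo
checks, 200 random substrates for the enumeration oracle) were chosen to
keep the whole validation desk-scale while leaving the statistical checks
well-powered.

```{r endtoend, eval = FALSE}
scn <- krasScenario()
bundle <- generateDesignBundle(scn$design, scn$digestCfg, scn$chromCfg,
                               seed = 7)
res <- runSplicePipeline(bundle, scn, seed = 7)
res$rtResolved
subset(res$identifications, time_point_h %in% c(0, 4))
```

## Known limitations

* Scores are surrogates: no attempt is made to reproduce a commercial
  search engine's ion score or its q-value machinery; q-values are
  consumed, with a target-decoy helper provided only for synthetic runs.
* The shared/diagnostic ion partition is purely mass-window based; how a
  display layer would resolve near-isobaric theoretical ties is not
  modelled.
* MS1 input is centroided scans (CSV or MGF-like); vendor RAW and
  profile-mode mzML are out of scope, as are chromatographic alignment
  across runs and isotope-pattern-aware quantification.
* Enumeration is per-substrate; whole-proteome candidate databases are out
  of scope.
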