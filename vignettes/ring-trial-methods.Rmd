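---
title: "Methods: proficiency statistics for diatom metabarcoding ring trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proficiency statistics for diatom metabarcoding ring trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomRing)
```

## The setting

A ring trial circulates identical calibrated samples — a lake biofilm
(`L`), a river biofilm (`R`), a mock community of 12 cultured diatom
strains (`M`) and a DNA-free water blank (`W`) — to a panel of
laboratories. Each lab performs one step of the metabarcoding workflow
(DNA extraction or PCR amplification) with either a fixed common protocol
(proficiency test) or its own protocol (method comparison). After central
sequencing and bioinformatics, each sample is a vector of taxon read
counts. `diatomRing` covers everything downstream of taxonomic
assignment: filtering, diversity and index computation, proficiency
statistics, anomaly diagnosis and community-level variance partitioning.

The design is encoded as a `DesignSpec` and expanded into a manifest of
sample units keyed `experiment/participant/sample_type/replicate`
(e.g. `"E2/G/L/1"`). Keys are the join column throughout, so a single
table file is self-describing. Sequencing-inclusion rules are explicit:
blanks are sequenced only when listed as exceptions (they then become
*false-positive controls*), other units unless their amplicon failed.
`designAccounting()` reproduces the unit bookkeeping of a trial from
these two lists alone. The reference laboratory is modelled as an
ordinary participant (`"RL"`) in a `REF` pseudo-experiment: in a
consensus-scored proficiency test it has no privileged role. The
identities of the nine method-comparison labs are anonymous in published
ring trials; `studyDesign()` fixes a deterministic subset, which leaves
every count invariant.

## Filtering rules

`discardNonTarget()` removes rows assigned outside the target phylum
(default `Bacillariophyta`) and rows labelled
`<phylum>_unclassified`. `filterLowAbundance()` implements the
low-abundance rule as a *conjunction applied per cell*: a count is zeroed
when it is below `min_reads` (default 10 reads) **and** below
`min_fraction` (default 1e-4, i.e. 0.01 %) of its sample's pre-filter
read total. Two genuinely open readings are provided as switches rather
than silently chosen: `rule = "or"` (disjunction) and `per = "taxon"`
(a taxon is dropped everywhere when even its best cell fails). Fractions
are always tested against pre-filter totals — the filter is applied once,
not iteratively. Empty samples are kept and reported, never tested.
Relative abundances are stored as fractions in `[0, 1]`; columns of a
relative table must sum to 1 within 1e-9 (class invariant, enforced at
construction).

## Diversity and variability

Hill numbers unify richness and evenness on one scale of effective taxon
counts: `D(q) = (Σ pᵢ^q)^(1/(1−q))`, with `D(1) = exp(−Σ pᵢ ln pᵢ)` taken
whenever `|q − 1| < 1e-6` so the function is continuous in `q`. Orders 0,
1 and 2 are computed per sample at both ASV and species level, since
genetic and taxonomic richness answer different reproducibility
questions. The coefficient of variation uses the sample (n−1) standard
deviation — panels are small, and that is the convention of
inter-laboratory studies — and is reported in percent. Replicates are
averaged within a participant before the CV across participants is taken,
so the CV measures between-lab variability only.

## Quality indices

National index databases are licensed and cannot be redistributed, so the
package ships the index *computations* plus a synthetic trait generator,
and an importer for user-supplied trait tables.

* **IPS-type score.** The Zelinka–Marvan weighted average
  `raw = Σ aⱼ sⱼ vⱼ / Σ aⱼ vⱼ` over taxa with traits, where `s ∈ [1, 5]`
  is sensitivity and `v ∈ {1, 2, 3}` the indicator (stenoecy) weight,
  mapped to the 1–20 reporting scale by `4.75·raw − 3.75`.
* **IBD-type score.** Class loadings `Fᵢ = Σₓ aₓ Pₓᵢ vₓ / Σₓ aₓ vₓ` over
  seven water-quality classes with increasing scores `c₁ … c₇` (default
  1–7), barycentre `B = Σ Fᵢcᵢ / Σ Fᵢ`, mapped affinely from `[c₁, c₇]`
  to `[1, 20]`.

Abundances are renormalised over the trait-covered taxa rather than
penalising missing traits; the covered fraction is reported as
`coverage`, and a score is flagged invalid below a configurable minimum
(default 0.7 — practice requires "enough" contributing taxa but no
universal number exists, so the cutoff is explicit and surfaced rather
than hidden). Scores are clamped to `[1, 20]` with clamp events recorded.
Status classes use half-open intervals closed at the top:
`[17, 20]` high, `[13, 17)` good, `[9, 13)` moderate, `[5, 9)` poor,
`[1, 5)` bad.

## Proficiency statistics

z-scores follow the classical ring-trial definition
`z = (x − μ)/σ` with `μ` and `σ` the plain mean and sample SD over *all*
participants, the scored one included — fidelity to the standard formula
first; median/MAD robust estimators are available behind `robust = TRUE`
but off by default. Zones: `|z| ≤ 2` in control, `2 < |z| ≤ 3` warning,
`|z| > 3` action; the panel fails iff any participant is in the action
zone. When every lab returns the same score, `σ = 0` is not an error but
the best possible outcome: all z are defined 0 and flagged
`degenerate_dispersion` (this is exactly the structure of a consistent
top-score index across a panel). Note an arithmetic constraint worth
knowing when designing panels: a single outlier among `n` labs can reach
at most `|z| = (n−1)/√n`, so the action limit is only attainable for
`n ≥ 11`.

The Youden construction rotates the paired river/lake z-scores by 45°:
`u = (z_R + z_L)/√2` measures a shared (systematic) shift, `v = (z_R −
z_L)/√2` the item-specific (random) scatter; the rotation is an isometry,
asserted in the tests. Classification: outside the 3 SD box, `|v| ≤
line_tol` is a systematic error, otherwise a total error; inside the box
`|v| > line_tol` is a random error. `line_tol` defaults to 2, mirroring
the 2 SD warning convention — the visual notion of "close to the 45°
line" needs a number, and this is the one consistent with the zoning.
The plotting layer receives a 95 % circle of radius `sqrt(qchisq(0.95,
2))` on the standardised axes; a fitted ellipse would presume a
correlation structure the panel sizes cannot support, so the circle is
the documented assumption.

Detection thresholds: for each taxon the *representative abundance* is
its maximum relative abundance over the labs that detect it (the mean
variant is also computed — which convention underlies published
thresholds is ambiguous, so both are reported); the threshold is the
largest representative abundance among taxa missed by at least one lab.
The defining guarantee — every taxon strictly above the threshold is seen
by all labs — is verified by brute-force enumeration on every simulated
test dataset.

Anomaly diagnosis works on composition alone. `matchComposition()`
returns the Bray-Curtis-closest reference community (ties broken by
lexicographic name, documented and deterministic). `fitMixture()`
projects the query onto the segment between two references: the
least-squares mixing fraction has the closed form
`α = ⟨q − B, A − B⟩ / ‖A − B‖²`, clipped to `[0, 1]`; the residual is the
Bray-Curtis distance to the fitted mixture, and a unit is flagged
`mixture_suspect` when the residual is below 0.05 and `α ∈ [0.2, 0.8]`.
A sequenced blank matching a community within 0.05 is a
`swap_suspect` — the pipetting-error signature.

## Community statistics

Bray-Curtis dissimilarity `1 − 2Σmin(xᵢ,yᵢ)/(Σxᵢ+Σyᵢ)` is symmetric with
identity of indiscernibles but not a metric (no triangle inequality).
Distance matrices are computed by `vegan::vegdist`; nMDS by
`vegan::metaMDS` (monotone-regression monoMDS engine) behind
`nmdsOrdination()`, with coordinates centred, principal-axis rotated and
sign-fixed so a seed pins the embedding exactly.

PERMANOVA and MRPP are implemented in-package to give the permutation
machinery an explicit contract: the one-factor Anderson partition of
squared distances (pseudo-F, `R² = SS_between/SS_total`), MRPP's
group-size-weighted mean within-group distance `δ` and chance-corrected
`A = 1 − δ/E[δ]` (with `E[δ]` the analytic permutation expectation, the
overall mean distance). The p-value is `(1 + #{stat_perm at least as
extreme})/(1 + n_perm)` for the Monte-Carlo route — it can never be 0,
matching "p < 0.0001"-style reporting at 9999 permutations — and switches
automatically to full enumeration of all `n!` label permutations when
that count is at most 10,000 (n ≤ 7), where the p-value is exact.
Singleton groups have no within-group distance; MRPP excludes them with a
report. Both statistics are cross-checked against `vegan::adonis2` and
`vegan::mrpp` in the test suite, and Monte-Carlo p-values against
exhaustive enumeration. Only the one-factor design is provided — the
ring-trial factors are participant or method, never nested.
Kruskal-Wallis tests go through `stats::kruskal.test` (tie-corrected H,
χ² approximation), with the all-identical case defined as `H = 0, p = 1`.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, plus a ground-truth record, so that every downstream stage has
a testable oracle.

* **Reference communities.** Geometric rank-abundance series by default
  (`k = 0.8`, so the i-th ranked taxon has abundance ∝ `k^(i−1)`), 30
  taxa in `R` and `L` with 40 % of the smaller community shared, a
  12-taxon mock `M` on disjoint taxa, and an empty `W`. True abundances
  of calibrated field samples are unknown; a geometric series is the
  standard parsimonious model and creates the abundant/rare split that
  detection-threshold analysis needs. A lognormal alternative is built
  in.
* **Lab effects.** Systematic bias acts multiplicatively on the log
  scale — `p′ ∝ p·exp(bias + ε)` — matching the taxon-efficiency biases
  of extraction and PCR; `ε` is iid normal replicate noise (default sd
  0.05, a mild but visible between-replicate wobble). Optional dropout
  removes below-floor taxa with a stated probability. Counts are
  multinomial at the configured depth (default 10,000 reads/sample, the
  per-sample scale of a typical MiSeq ring-trial run), so column sums
  are exact by construction.
* **Anomalies.** A `swap` replaces a unit's community wholesale (the
  blank-contamination signature), a `mixture` replaces it with
  `α·A + (1−α)·B` (the 1:1 mix signature at `α = 0.5`), `contamination`
  blends a fraction of a source into the unit's own community.
* **Seeding.** One master seed; each unit draws from a substream seeded
  by a hash of the unit key, so results are independent of unit
  insertion order and any subset of units reproduces bit-identically.

What the generator does *not* emulate: read-level error (no FASTQ,
chimeras or denoising artefacts), taxonomic misassignment,
between-community trait correlation, or the heavy-tailed depth variation
of real runs. Passing recovery tests therefore demonstrates that the
*statistics* behave as specified under the stated error model — not that
any particular wet-lab protocol is reproducible.

Published lab-effect magnitudes do not exist, so the recovery conditions
fix a documented effect size rather than an estimate: the faulty lab
receives a trait-aligned bias of ±1.5 log units (over-amplifying
sensitive taxa with `s ≥ 4`, under-amplifying tolerant ones with
`s ≤ 2`), a clearly protocol-level fault that shifts its index score by
a large multiple of the between-lab spread, while replicate noise stays
at sd 0.05 for everyone. Under these conditions the faulty lab must be
flagged (`|z| > 2`) and Youden-classified systematic in at least 90 % of
seeded panels and unbiased labs flagged in at most 10 % — both asserted
over 50 seeds in the acceptance tests.

## Numerical conventions and degenerate inputs

* Relative columns sum to 1 within 1e-9; trait profiles within 1e-6;
  aggregation conserves counts exactly and fractions to 1e-12.
* Empty profiles: Hill numbers return flagged 0; CV with zero mean is
  flagged undefined; Bray-Curtis of two empty vectors is flagged NA.
* Zero trait coverage yields an invalid index result with no score, not
  an exception; `σ = 0` yields flagged z = 0, not an exception.
* Identical mixture references make `α` undefined (flagged).
* Ties in `matchComposition` break lexicographically; nMDS sign/rotation
  are pinned as described; permutation p-values are bounded below by
  `1/(1 + n_perm)`.

## Problem sizes

The test-suite and acceptance-script simulations use 17-lab panels at
depth 10,000 (proficiency recovery, 50 seeds), depth 1e5 for anomaly
recovery, 6-lab × 3-replicate panels at depth 5,000 for the
method-comparison partition, and n ≤ 7 instances for exhaustive
permutation oracles — sizes chosen to exercise the statistics at the
study's panel scale while keeping a full run in the order of seconds.

## Limitations

The package consumes assigned taxon tables; denoising, chimera removal
and classification are upstream. Index scores from the bundled synthetic
trait table are for pipeline exercise only and carry no ecological
meaning — supply a real trait table for assessment work. The proficiency
statistics implement consensus scoring (mean/SD over participants), not
the full homogeneity/stability machinery of formal PT standards; and
one-factor PERMANOVA deliberately omits nested or stratified designs.
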