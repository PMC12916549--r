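---
title: "Mapping introgressed chromatin from low-pass GBS coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping introgressed chromatin from low-pass GBS coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introcov)
```

## The model

An interspecific introgression line (here: bread wheat carrying barley
chromatin) is sequenced at low pass and its reads are aligned to an
*in silico hybrid* reference — the two parental assemblies concatenated, so
that reads partition between the wheat and barley subgenomes. `introcov`
models the outcome purely at the level of per-Mb-bin read counts:

* each bin has a latent copy number `cn ∈ {0, 1, 2}` in the line's
  karyotype (euploid recipient bins are 2, donor bins 0, introgressed
  donor bins 2, monosomic material 1);
* the expected raw count of bin `b` is
  `λ_b = depth · (cn_b / 2 + c_sub) · len_b`, where `depth` is the expected
  count of a fully present disomic bin, `c_sub` is a small subgenome-specific
  cross-mapping rate (conserved sequence attracting reads from the other
  subgenome), and `len_b` is the bin's length fraction (a trailing partial
  bin);
* normalized coverage divides raw counts by `M · len_b`, with `M` the
  median nonzero bin count, so present disomic bins centre near 1.0 and
  absent bins near the cross-mapping rate.

Presence/absence is then a two-state classification of the normalized
profile, and structural interpretation (which arms are present, which
fusion that implies, what was deleted) is arithmetic on the resulting
segments.

## Why the median of nonzero counts

The normalization constant is deliberately *not* the mean over all bins: in
a translocation line a large fraction of bins (a whole absent arm, the
six non-introgressed donor chromosomes) is near zero, and the mean would
shift with karyotype. The median over nonzero bins is dominated by the
present euploid majority and is insensitive to the absent fraction, which
is what lands present bins at ≈ 1.0 regardless of how much chromatin a
line lost. A `mean_top_half` alternative is exposed behind a flag for
profiles where more than half of the nonzero bins are background.

## Segmentation parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tau_absent` | 0.15 | normalized coverage | absent bins in real skim data stay ≤ 0.23 even inside deleted regions; 0.15 sits above the typical 0.002–0.013 background with margin |
| `tau_present` | 0.4 | normalized coverage | present bins stay ≥ 0.5 per chromosome region; 0.4 leaves room for Poisson dips at depth ~30 |
| `min_run` | 3 | bins (Mb) | absorbs isolated one/two-bin dropouts while preserving the smallest real block the method must resolve (28 Mb) |
| `min_deletion_mb` | 5 | Mb | absent runs shorter than this are more plausibly smoothing artefacts than real deletions |

Bins strictly between the thresholds are *intermediate* and are resolved to
the state of the nearer resolved flank on the same chromosome; at equal
distance, to the flanking run whose mean normalized value is closer to the
bin's own. A chromosome that is entirely intermediate falls back to the
threshold midpoint. Segmentation is threshold-plus-smoothing rather than an
HMM: at this signal-to-noise (present and absent bins separated by nearly
two orders of magnitude) a deterministic, auditable rule recovers block
boundaries at bin resolution, and every call can be traced to the bins that
produced it. An HMM would become worthwhile only at substantially lower
depth or with mosaic (sub-bin) events, both outside this design.

## Event calling

**Arm status.** Each arm's fraction of present chromatin is thresholded at
0.9 (present) / 0.1 (absent). On the wheat side of a fusion call these
strict thresholds apply. On the barley side the package uses a relaxed,
symmetric 0.75/0.25 rule: a pericentric inversion can move a few tens of Mb
across the centromere, so the donor arm travelling into the fusion may
carry, e.g., only 217 of its 253 Mb (fraction 0.86) while the opposite arm
retains a small orphan block (fraction 0.14). The line is still named by
arm, as the field does.

**Deletions** are called only on recipient (wheat) chromosomes that are
majority-present and have no fully absent arm: a lost arm is fusion
geometry, and absent stretches on a donor chromosome delimit the
introgression rather than damage the background. Each surviving absent
segment ≥ 5 Mb becomes a call, `terminal` if it touches a chromosome end.

**Pericentric inversion inference** needs two *complementary* carrier
lines of the same donor chromosome (their present sets must overlap by at
most 5% of the chromosome and jointly cover ≥ 95%). A clean centric
fission — each carrier holding one terminal run — yields no call. The
inversion signature is the 2×2 crossover: one carrier holds
`[0,p) ∪ [q,r)`, the other `[p,q) ∪ [r,L)`, with the centromere inside
`[p,r)`. Then the two interior blocks swapped sides before the fission, and
the call reports interval, block lengths and centromere spanning. Noisier
patterns (three or more present runs) return a diagnostic, not a call —
deliberately conservative, since coverage alone cannot distinguish an
inversion from assembly mis-ordering near the centromere; the call is
"putative" by construction. The inference is symmetric in the order of the
two lines.

## The simulator and the packaged scenarios

The generator emulates low-pass GBS coverage statistics, not sequences:
per-bin counts are `Poisson(λ_b · m_b)` with a unit-mean gamma mappability
factor `m_b` (variance `mappability_dispersion`, default 0.005), i.e. a
negative-binomial-like marginal. Defaults are `depth_per_bin = 30`,
cross-mapping 0.011 onto barley and 0.004 onto wheat — the midpoints of the
background ranges observed in real skim data (0.009–0.013 and
0.002–0.006). At depth 30 the per-bin spread of present bins is dominated
by Poisson counting noise (CV ≈ 0.18); the gamma factor adds the smaller
bin-to-bin mappability wobble that persists at high depth. A read-position
mode scatters the same per-bin multiplicities uniformly within bins so the
counting stage can be tested end-to-end; by construction it reproduces the
count table exactly under the same seed.

Three scenarios ship with the package, encoding the karyotypes of
wheat–barley centric fusion lines on a 28-chromosome reference
(21 wheat + 7 barley, 18,509 one-Mb bins):

* `T6HS.6BL` — 6BS (345 Mb) lost, short-arm 6H chromatin present as
  `[0,217) ∪ [253,281)` (245 Mb, 44% of the 560-Mb chromosome);
* `T6BS.6HL` — the complementary line, 6H present as
  `[217,253) ∪ [281,560)` (315 Mb, 56%);
* `T4BS.4HL` — 4BL (last 356 Mb) lost, 4HL (last 335 Mb) gained, plus two
  background deletions: interstitial `[573,622)` on 2D and terminal
  `[724,851)` on 3B.

The two 6H scenarios are generated from a single `pericentric_inversion`
event on `[217,281)` followed by an `arm_replacement`: the inversion
re-tags which physical blocks travel with each arm (bins before the
centromere become long-arm travellers and vice versa), so the complementary
present sets and the 64-Mb inversion call fall out of the event model
rather than being hard-coded. The 6H centromere is placed at 253 Mb, the
boundary between the two swapped blocks — consistent with the block
geometry, but a modelling choice, since the donor assembly's centromere
coordinate is not part of the scenario data. One published figure gives the
6H total as 560 Mb and another as 561 Mb; the scenarios use 560, the sum of
the four block lengths.

Chromosome lengths for scenario-relevant chromosomes are fixed by the block
coordinates above (6B 731, 6H 560, 3B 851, 2D 665, 4B 673, 4H 647 Mb); the
remaining 22 entries of the default table are representative values at
realistic assembly scale, and no result depends on them beyond bin totals.

### What the simulator does not emulate

No restriction-site digest model (real GBS counts cluster near enzyme
sites), no mapping-quality structure, no concentration of cross-mapping in
conserved regions (the background is flat), no sequence-level errors. A
segmentation that passes on simulated data has been shown to invert the
generator's own noise model at realistic depth and geometry — evidence of
correctness of the algorithmic chain, not a guarantee on any particular
real library. The printed normalized values of real lines (e.g. 1.079 on a
real 6HS region) depend on undeposited raw reads and an external
normalization protocol; they calibrate the simulator's ranges and are not
reproduced.

## Numerical and degenerate-input choices

* Bin assignment uses the read start only; coordinates are 0-based
  half-open internally, and printed labels are 1-based inclusive
  (`[217,253)` → "218-253 Mb") to match the field's reporting style, whose
  off-by-one conventions vary; block *lengths* are the stable quantity.
* All-zero coverage refuses to normalize ("no informative bins").
* A single seeded RNG stream drives each simulation; bins are consumed in
  reference order, so partial re-simulation is not supported — simplicity
  over resumability.
* SAM text input filters to mapped records with MAPQ ≥ 20 — an explicit
  package default, since quality-filter parameters are protocol-specific.
* Smoothing iterates leftmost-first to a fixpoint and never flips runs
  touching a chromosome end; with two states, the fixpoint leaves no
  interior run shorter than `min_run`.

## Problem sizes used in the test suite

The suite simulates the full 18,509-bin reference (sub-second per
replicate); the boundary-recovery property uses 20 seeds at depth 30 and
requires ≥ 95% of the three 6H block boundaries within ±1 bin. Large-sample
statistical checks (dosage means, cross-mapping rate) use 3,000–10,000-bin
toy chromosomes and three-standard-error bands.

## Limitations

* Resolution is the bin (1 Mb); no sub-bin breakpoint refinement.
* Copy number is saturated at 2; amplifications are out of scope.
* Monosomic material simulates at half depth (normalized ≈ 0.5) and the
  default `tau_present = 0.4` classifies it *present*; callers targeting
  monosomic/disomic dosage should inspect segment means, not states.
* The inversion caller reports the rearrangement, not its origin (whether
  it pre-exists in the donor cultivar or arose with the translocation
  cannot be decided from these two lines).
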