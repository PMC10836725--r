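---
title: "Designing and deconvoluting pooled minigene screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and deconvoluting pooled minigene screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
library(dplyr)
```

## The problem

Matching a T cell receptor (TCR) to its cognate antigen requires expressing
many candidate antigens in antigen-presenting cells and reading out which one
activates a reporter T cell. poolscreen covers the computational side of that
workflow:

1. **Library design** — proteins are tiled into overlapping minigene
   fragments (up to 400 amino acids each) so that natural processing can
   present any internal epitope; programmed substitutions emulate
   post-translational edits such as the Q→E deamidation that creates celiac
   disease epitopes; fragments are assembled behind an N-terminal
   processing-enhancing leader and, after a hit, refined into progressively
   smaller overlapping fragments until the minimal epitope interval is
   bracketed.
2. **Backtranslation** — each amino-acid sequence is converted to
   synthesizable DNA under codon-usage weighting and synthesis constraints.
3. **Pooled-array design** — constructs are distributed over wells so that
   the pattern of activated wells uniquely identifies the cognate construct
   without sequencing.
4. **Readout analysis** — well signals become Z-scores, replicates are
   aggregated, positive wells are called and the design is inverted.
5. **Simulation** — every input above can be generated with known ground
   truth, so the full pipeline is testable offline.

## Tiling and coordinates

All coordinates are 1-based and inclusive: a fragment labelled `612-1011`
has length 400. `tile_protein()` returns the *minimum* number of fragments
of length at most `window` covering the protein with adjacent overlaps of at
least `min_overlap`:

$$n = \left\lceil \frac{L - w}{w - v} \right\rceil + 1 \quad (L > w),$$

with protein length $L$, window $w$ and minimum overlap $v$. The defaults
(`window = 400`, `min_overlap = 30`) reflect the practical minigene ORF size
and the longest epitope one would not want to split across a fragment joint.
When the slack $(L - w)$ does not divide evenly, the extra overlap is spread
as uniformly as possible across junctions, deterministically — the layout for
a 1315-residue protein is `1-400, 306-705, 611-1010, 916-1315` with uniform
overlaps of 95.

`refine_fragment()` re-applies the same layout rule inside a positive
fragment with the child window
$\lceil (\mathrm{len} + (c-1)\,v) / c \rceil$ for `n_children` $c$. The
defaults (binary splits, `min_overlap = 15`, `min_length = 20`) keep any
class II epitope of up to 15 residues intact across junctions and stop
refinement at fragments that electroporation-scale validation would take
over. `epitope_interval()` intersects the positive intervals at the deepest
tested level; disjoint positives raise an explicit multi-epitope signal
rather than returning a misleading interval, because large fragments can
legitimately carry several distinct epitopes.

## Constrained backtranslation

The amino-acid → DNA converter draws each codon from the packaged human
codon-usage table (codons rarer than `min_codon_frequency = 0.02` within
their amino acid are never used), then repairs violations of the synthesis
constraints:

| constraint | default | rationale |
|---|---|---|
| GC per 50-nt window | 0.40–0.60 | synthesis vendors reject GC excursions; the lower bound doubles as the AT-rich guard |
| pyrimidine (C+T) per 30-nt window | ≤ 0.75 | pyrimidine-rich stretches impair synthesis |
| homopolymer run | ≤ 5 nt | longer runs cause slippage |
| forbidden motifs | SpeI `ACTAGT`, BamHI `GGATCC`, both strands | cloning sites must stay unique to the vector flanks |

The windowed thresholds are package choices — no published values exist for
this step — and every one is configurable via `backtranslation_config()`.
Repair proceeds by sweeps: each sweep rescans the sequence, selects
well-separated violation regions, and applies for each the synonymous
single-codon swap that most reduces a local penalty (ties broken by codon
frequency, then alphabetically); when no swap helps, the window is resampled,
widening with consecutive stalls so the search escapes local minima. The
result is deterministic for a fixed seed, and `validate_dna()` — an
independent exhaustive scanner, not the generator's bookkeeping — must pass
on every output.

Windowed bounds cannot be satisfied by *every* protein: ten consecutive
phenylalanines force a pyrimidine-saturated window no codon choice can fix.
`backtranslate()` detects such composition infeasibilities up front from
per-residue codon extremes over codon-aligned windows and refuses with an
explicit error naming the stuck residues; it never silently emits a
violating sequence. On uniform random proteins such refusals occur for
roughly one sequence in a thousand.

`batch_backtranslate()` derives a per-record seed from the batch seed and
the record id, so a record's output is independent of batch composition and
order, and per-record failures are collected instead of aborting the batch.

## Pooled-array design

`design_pools()` assigns each target to `min_replicates` wells such that no
two targets co-occur in more than one well and no well exceeds
`pool_size_max` targets. With at least two replicates, pairwise
co-occurrence ≤ 1 forces all well-signatures to be distinct — two targets
sharing their whole (≥ 2-well) signature would co-occur at least twice — so
the set of activated wells identifies the target uniquely.

For two replicates the problem is exactly edge placement in a simple graph
on `n_wells` vertices with maximum degree `pool_size_max`: feasible if and
only if

$$n_\mathrm{targets} \le \min\!\left(\left\lfloor \tfrac{n_\mathrm{wells} \cdot
\mathrm{pool\_size\_max}}{2} \right\rfloor,\; \binom{n_\mathrm{wells}}{2}\right).$$

A naive greedy edge placement can strand a vertex short of this frontier, so
the solver realizes a maximally even degree sequence with the Havel–Hakimi
construction, which provably succeeds everywhere in the feasible region;
seeded permutations of well labels and target order vary the layout without
touching feasibility. For more than two replicates a seeded greedy with
chronological backtracking assigns well-sets under the same pairwise
constraint. `verify_design()` re-derives every guarantee by brute force over
all target pairs and shares no code with the solver.

`to_plate_layout()` mirrors the bench workflow: each source pool (e.g. a
96-well lentivirus pool at 65 ng per construct, 0.325 µg for a pool of
five) is split onto `technical_replicates` adjacent assay wells of a 384-well
coculture plate, row-major.

## Readout analysis

* **Overton percent-positive.** With sample and control histograms on shared
  binning and normalized to unit area, the statistic is
  $100 \sum_b \max(0, f^{s}_b - f^{c}_b)$ — the sample area not overlapped by
  the control. It is 0 for identical distributions, approaches 100 for
  disjoint supports, and recovers the mixing fraction of a clearly shifted
  subpopulation. Raw event vectors are binned into 256 equal-width bins over
  the pooled range by default. Between two finite samples of the *same*
  distribution the positive-part sum has an upward bias of order
  $\sqrt{\mathrm{bins}/n}$; null comparisons should use wide bins or large
  event counts.
* **Z-scores.** Each well is standardized against all wells of the
  experiment, using the population (1/n) standard deviation, so the scores
  have exactly mean 0 and SD 1.
* **Replicate aggregation.** Technical replicates are combined by a shifted
  geometric mean, $\exp(\mathrm{mean}(\log(z + o))) - o$ with offset
  $o = 10$ by default, since Z-scores can be negative; the offset must keep
  every shifted value positive and is configurable.
* **Calling and deconvolution.** Pools with aggregated score at or above
  `z_threshold` are positive; `deconvolute()` scores each target by the
  fraction of its signature that is positive, ranks by support, then by fewer
  extra positive wells, then by id, and flags full-support candidates as
  exact. Partial-support candidates are reported deliberately, so screens
  with a false-negative well still surface near-misses for review.

**Choosing the threshold.** The default `z_threshold = 3` follows the usual
plate-screening hit convention and suits production-scale arrays, where hit
wells are a small minority. At pilot scale the convention breaks down
arithmetically: with 18 targets in 8 wells, the two hit wells themselves
inflate the experiment-wide standard deviation, capping the attainable
Z-score near 1.7 even without noise. Analyses and tests at that scale
therefore pass `z_threshold = 1` explicitly. The threshold applies to the
replicate-aggregated score, not to individual wells — aggregation first
suppresses single-replicate artifacts.

## The simulator and what it does and does not show

`simulate_screen()` draws hit wells from $\mathcal N(\mu_+, \sigma)$ and
background wells from $\mathcal N(\mu_-, \sigma)$, floored at zero
(defaults $\mu_+ = 10$, $\mu_- = 1$, $\sigma = 1$, chosen as a clean
ten-fold activation window over background typical of reporter readouts; a
log-normal variant is available behind a flag). Dropout — a positive pool
reading as negative with probability `dropout_rate` — acts on the *source*
pool, so both technical replicates fail together, mirroring the 96-to-384
split in which replicates derive from a single transduction well. Signal
noise is drawn independently per replicate. `simulate_flow_events()`
generates log-normal intensities (matching the log-scaled appearance of
cytometry data) with a known shifted fraction, and `simulate_well_image()`
places non-overlapping discs with an exact ground-truth mask.

The simulators establish algorithmic correctness: that the analysis inverts
the design, that recovery degrades monotonically with noise and dropout,
and that the Overton statistic recovers known mixture fractions. They do not
model spatial plate effects, correlated well failures, reporter saturation,
partial activation by near-cognate antigens, or cell-morphology realism —
passing tests say nothing about those aspects of real screens.

## Numerical and scale choices

Tests exercise tiling on random proteins up to 5000 residues; backtranslation
round-trips on 1000 random proteins of 30–150 residues plus one
10,000-residue protein for codon-usage convergence; array designs across the
full two-replicate feasibility frontier for 4–10 wells; exhaustive noiseless
deconvolution of every target across 20 design seeds; and a 3 × 3
noise-by-dropout grid with 100 simulations per cell using common random
numbers. These sizes were chosen to make every guarantee observable at
desk scale. Ties in the repair loop, in candidate ranking and in tiling are
all broken deterministically, so every result is reproducible from its seed.

## Limitations

* The pooled design guarantees unique signatures for a *single* true target;
  multiple simultaneous hits are reported (all exact candidates) but the
  design does not error-correct false-negative wells.
* Backtranslation optimizes constraint satisfaction plus usage weighting
  only; mRNA secondary structure, codon-pair bias and vendor-specific rule
  sets are out of scope.
* Overton subtraction assumes identical instrument conditions for sample and
  control; no compensation or gating is performed.

## A worked pilot screen

```{r pilot}
design <- design_pools(n_targets = 18, n_wells = 8, pool_size_max = 5,
                       min_replicates = 2, seed = 1)
verify_design(design)

sim <- simulate_screen(design, true_targets = "T13", seed = 7)
result <- analyze_screen(sim$readouts, design, z_threshold = 1)
glance(result)
tidy(result) |> head(3)
```

The positive wells are exactly the true target's signature, and the single
exact candidate is the simulated truth.
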