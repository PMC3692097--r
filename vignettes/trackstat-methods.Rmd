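---
title: "Statistical analysis of genomic tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical analysis of genomic tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The track abstraction

Genome-scale data sets — genes, transcription-factor binding sites, histone
modification domains, per-bp signal — can all be represented as *genomic
tracks*: elements positioned on the coordinate line of a reference
assembly. Once two data sets live on the same line, a biological question
("do binding sites prefer active chromatin?") becomes a precise statistical
question about the relation of two element sets.

`trackstat` implements five geometric track types: points (`P`), segments
(`S`), valued points (`VP`), valued segments (`VS`) and functions (`F`, a
numeric value for every covered bp). Values come as numbers, case/control
labels or categories. Internally all coordinates are 0-based, half-open
(`[start, end)`, the BED convention); WIG and 1-indexed GTrack input is
converted at the I/O boundary, so exactly one convention exists inside the
package. A point is a single bp position, not a length-1 segment;
containment of point *p* in `[s, e)` means `s <= p < e`. Strand is parsed
and carried as metadata but ignored by all statistics except anchor
aggregation (and the opt-in `stranded` flank expansion), since none of the
implemented analyses is inherently strand-dependent.

Analyses are evaluated *per bin* — an ordered set of non-overlapping
analysis regions, usually a fixed-size split of the genome — and globally.
Bins are the unit of "local" results and also the unit of randomization.

## Null models

A hypothesis test needs an explicit notion of "expected by chance". The
package makes the randomization scheme a first-class object
(`null_model_spec()`):

* **uniform_independent** — points are re-drawn i.i.d. uniformly within
  their bin (with replacement, matching the continuous-genome intuition
  that coincidence has measure zero); segments keep their per-bin length
  multiset and are placed without overlap, uniformly over *all feasible
  arrangements*. The placement uses gap-composition sampling: the free
  space `L - sum(len)` is split uniformly at random among the `n + 1` gaps
  (a uniform draw over compositions, realized by sampling `n` distinct
  cut positions), and the segment order is permuted. This makes every
  non-overlapping arrangement equiprobable, which we verify against
  enumeration in the tests.
* **preserve_gaps** — the multisets of inter-element gaps and element
  lengths are kept, their order is permuted, and the leading offset is
  re-drawn uniformly over the slack. This preserves the empirically
  observed clustering tendency (the gap distribution) while destroying
  position. Whether the first offset should be fixed or re-drawn is a
  genuinely open choice; we re-draw, so that the randomization has no
  anchored element.
* **intensity_guided** — points are drawn per bin from a per-bp weight
  distribution (an intensity track), *without* replacement, because the
  intensity assigns probability mass to discrete positions.
* **permute_labels / permute_values** — positions stay fixed; case/control
  or category labels, or numeric values, are shuffled within the bin.
* **uniform_within_segments** — points are re-drawn uniformly inside their
  containing segment of a conditioning track; points outside every
  conditioning segment keep their position.

With `per_bin = TRUE` (the default) each bin is randomized independently,
preserving large-scale structure across the genome; `per_bin = FALSE`
randomizes within each maximal run of book-ended bins instead (elements
cannot be placed into gaps between non-adjacent bins). One root seed
produces deterministic per-bin child streams, so results are independent
of the order in which bins are evaluated, and identical specifications
reproduce bit-identical results.

### Intensity tracks for confounder control

`make_intensity_track()` estimates, for every bp, the probability that a
target element lands there, given confounder tracks (gene proximity, GC
content, ...). Each confounder is discretized into quantile strata
(default 10; confounders with few distinct values stratify exactly by
value); the joint stratum of a bp is the tuple of its per-confounder
strata, and the weight is the empirical target density
`(# target points in stratum) / (# bp in stratum)`, normalized to sum to
one per bin. When the joint strata count would exceed `1e4` the estimator
falls back to a product of marginal density ratios. The histogram
estimator was chosen over smoother alternatives because it is transparent
and directly testable: a constant confounder provably yields the exact
uniform distribution.

## Test statistics

Each of the fifteen questions maps to a scalar statistic per bin
(`compute_statistic()`), e.g. intersection bp for overlap, inside counts
for containment, mean nearest-element distance with the sign flipped
(larger = closer) for proximity, mean `min(relpos, 1 - relpos)` for border
accumulation, best-Jaccard means for segment similarity, per-bp-normalized
case-minus-control differences for the preferential questions, and the
chi-square statistic of the category-by-category inside-count table for
differential co-location. Statistics whose natural scale is "smaller =
more effect" (border accumulation, nearby-value similarity) carry a
direction flag; the engine orients exceedance counting with it instead of
negating the reported value, so printed statistics stay on their natural
scale. The "similar segments" statistic (mean best Jaccard overlap of each
track1 segment with any track2 segment) is our interpretation of an
otherwise informal question and is flagged as such in reports.

Distances use one convention everywhere: elements are intervals (points
are zero-width), and the distance between two elements is
`max(0, s2 - e1, s1 - e2)` — 0 when they overlap or touch, otherwise the
bp gap.

## Monte Carlo evaluation and MCFDR

The Monte Carlo p-value uses the add-one permutation estimator
`(x + 1) / (n + 1)`, where ties between null and observed statistics count
as exceedances; it can never reach zero. One-sided alternatives count the
matching tail; the two-sided p-value is `min(1, 2 * min(p_more, p_less))`.

Sampling is sequential (the MCFDR scheme): null samples are added in
rounds of `chunk` per still-active bin; after every round the add-one
estimates are Benjamini–Hochberg adjusted across bins, and a bin stops
when

1. its exceedance count reaches `h` (the p-value is then precisely
   estimated and cannot become interestingly small), or
2. its BH-adjusted value drops to the FDR threshold `q`, or
3. it hits `max_samples`.

Defaults are `chunk = 100`, `h = 20`, `q = 0.05`, `max_samples = 10 000` —
chosen for desk-scale runtime and exposed as `mc_params()` flags. Under a
true null most bins stop after one or two rounds; the acceptance script
measures the saving (null bins typically use under 2% of the cap) and
verifies that rejection decisions agree with a fixed-`n = 10 000`
reference run.

The *global* statistic is tested with its own Monte Carlo stream in which
all bins are randomized jointly (the concatenation of per-bin
randomizations); it is never pooled from per-bin p-values.

The sequential stop-when-significant rule makes the estimator mildly
anti-conservative and the add-one rule with ties makes it conservative;
the net calibration is checked empirically: over 1000 independent
simulations of two uniform segment tracks the fraction of overlap-test
p-values at or below 0.05 sits inside the binomial band `[0.034, 0.066]`.

### Asymptotic routes

Where a standard closed form exists it is used by default (`evaluation =
"auto"`): the t-transform of Pearson's r for the correlation question, the
exact binomial (per bin, against the global proportion) for the
frequency-difference question, the chi-square upper tail for
category-by-category co-location, and Fisher's exact test for 2x2
case/control tables. The chi-square route is inherently two-sided
(omnibus); for the frequency-difference question the global asymptotic
p-value is the chi-square homogeneity test of the per-bin proportion
table. For frequency difference under Monte Carlo, the per-bin null is the
marginal hypergeometric distribution implied by a global permutation of
source labels; the global heterogeneity statistic
`sum_i k_i (prop_i - p_global)^2` is sampled from the joint permutation.
The per-bin/global pairing is our choice — the question names only the
comparison, not the mechanics.

### Default null models per question

Containment, overlap, proximity, border and similarity questions randomize
track1 positionally (uniform by default; gap-preserving and
intensity-guided selectable). Value questions permute values, label
questions permute labels, and the correlation question defaults to the
asymptotic route (a positional null for dense signal tracks is not well
defined; forcing Monte Carlo permutes the per-bp values of track2, which
destroys autocorrelation and is accordingly a stress test rather than a
faithful null — a known limitation).

## Descriptive conventions

* "Frequency" of points is points per bp of bin.
* Gap statistics are within-bin only (no cross-bin gaps), consistent with
  per-bin randomization.
* Coverage counts union bp of segments clipped at bin borders; length
  statistics use raw, unclipped segments, each assigned to the bin that
  contains its start.
* Variance is the unbiased (n-1) estimator throughout.
* Overlap enrichment per bin of length `L` is `c12 / (c1 * c2 / L)`; the
  global value sums per-bin observed and per-bin expectations, so
  heterogeneous bins do not bias it (a pooled formula would).
* Undefined per-bin values (empty required track, fewer than 2 gap
  points, constant correlation input) are flagged, never dropped silently,
  and excluded from the BH family.
* The category contingency table and the "matrix of counts inside" are the
  same computation at the descriptive level; they are implemented once.
  A point inside overlapping segments of different labels counts once per
  containing label and the result notes how many such points exist.

## Aggregation profiles

`aggregate_around_anchors()` splits every anchor into `n_subbins`
equal-length sub-bins — integer division, remainder bp to the leftmost
sub-bins, deterministically — computes the chosen statistic per sub-bin
per anchor, and averages across anchors with a normal-approximation 95%
confidence interval (`mean ± 1.96 * sd / sqrt(n)`; no bootstrap). CIs are
computed across anchors, not across positions, matching the averaging
semantics. Anchors shorter than the sub-bin count are skipped and tallied;
minus-strand anchors can be flipped so that sub-bin 1 is always 5-prime.

## Synthetic tracks

`simulate_track()` is the package's fixture generator and the basis of all
calibration experiments. It emulates: element counts apportioned by
chromosome length, segment lengths from a chosen distribution, clustering
through a geometric mixture of gaps (with probability `clustering` a short
within-cluster gap, otherwise a long gap scaled to span the chromosome)
and values from a chosen distribution. It does *not* emulate several
features of real annotation tracks: chromosome-end biases, correlated
occupancy between tracks, mappability holes, or heavy-tailed segment
lengths beyond what the supplied length distribution provides. Passing
calibration on these fixtures therefore demonstrates the correctness of
the machinery under its stated assumptions, not robustness to every
structure in real data — which is exactly why the null model is
user-selectable.

The calibration experiments use one 10 kb chromosome with 20 segments of
mean length 50 per track (a realistic density for, say, peak calls in a
large bin), 1000 replicates for type-I error, and a 100 x 1 kb bin genome
with 10 planted signal bins for the MCFDR comparison. These sizes were
chosen so a full validation runs on a laptop in minutes.

## Numerical and degenerate-input choices

* Midpoints are `floor((start + end) / 2)` — deterministic on the integer
  bp grid.
* Book-ended segments merge (`[0,5) + [5,8) = [0,8)`): zero-gap intervals
  are biologically contiguous.
* Point-anchored expansion produces `[anchor - upstream, anchor +
  downstream)`; zero flanks on a point anchor are an error (empty
  interval).
* k-mer matching counts overlapping occurrences; both-strand hits at the
  same position deduplicate to one point.
* GC windows must be odd (centered); the fraction is over defined (non-N)
  bases in the truncated window, and all-N windows are undefined.
* Intensity weights in a bin that sum to zero while the bin contains
  elements are a feasibility error, not silently uniform.
* Numeric values are serialized at full double precision (`%.17g`), so
  the text formats round-trip exactly.

## The batch language

Unquoted fields split on `/` into alternatives (cartesian expansion across
fields, `zip = TRUE` for lock-step); fields containing `*` are treated as
path globs under the track root, with `/` then acting as a path separator;
double-quoted fields are literal. This disambiguation is needed because
`/` serves both roles; quoting is the escape hatch. Every expanded command
writes a report with the tool, all parameters, input-file MD5 checksums,
the seed and the package version — enough to re-run any result exactly —
and one failing command never aborts the batch.

## Known limitations

* Linked/graph track types and 3D co-localization tests are out of scope.
* GTrack support is a pragmatic subset (type, value type, column and
  indexing headers); function tracks are serialized one bp per row, which
  is verbose for long signals — use WIG for those.
* variableStep WIG with `span > 1` and fixedStep with `step < span` are
  rejected rather than approximated.
* The correlation question has no faithful positional Monte Carlo null
  (see above); the asymptotic route assumes independent residuals, which
  per-bp genomic signal violates — p-values there should be read as
  screening values.
* `uniform_independent` for segments conditions on the per-bin length
  multiset; it does not model segment birth/death.
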