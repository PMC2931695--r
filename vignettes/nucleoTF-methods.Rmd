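---
title: "Methods and design notes for nucleoTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nucleoTF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleoTF)
```

# The model

nucleoTF treats nucleosome positioning as a two-class sequence problem.
Positive samples are 147-bp nucleosome core sequences; negative samples are
the linkers between successive cores. Each sequence is summarized by a
vector of TFBS-family densities — hits of any family member, on either
strand, divided by sequence length in bp — and the analysis asks which
families, jointly, best separate the classes, and in which direction each
family is enriched.

The pipeline makes the following assumptions:

* **Coordinates** are 1-based and inclusive on both ends, the convention of
  yeast nucleosome site tables; BED export converts to 0-based half-open.
* **Linkers are inter-core gaps only.** A gap before the first or after the
  last core of a chromosome is not flanked by nucleosomes on both sides and
  is never emitted. Overlapping or book-ended core calls are kept as-is (no
  merging) and simply produce no linker; merging would change the published
  core count, which downstream sample sizes depend on.
* **Strand symmetry is the scanner's job.** Sequences are extracted from
  the forward strand; the scanner counts hits on both strands, so the
  feature vector of a sequence equals that of its reverse complement (a
  property test asserts this).
* **Class labels** are 1 (core/nucleosome) and 2 (linker) end to end,
  matching the labeled matrix file dialect.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_len` (linker) | 6 | bp | shortest linker admitted as a negative sample; shorter gaps are steric noise between adjacent core calls |
| `max_len` (linker) | none | bp | the source data's published upper bound is stated inconsistently (two different values in different sections), so no cap is applied unless the user sets one |
| `t` (discretization) | 1 | — | three states at `mean ± t·sd`; t = 1 keeps roughly the central two-thirds of a unimodal feature in MID |
| `sd_type` | sample (n−1) | — | matches the default of standard statistical environments; switchable to population |
| MI base | 2 | bits | rankings are base-invariant (tested); bits are reported |
| `alpha` | 0.05 | — | significance threshold of the direction call |
| `block_size` | 2048 | rows | jackknife block width; affects memory/speed only, never decisions (tested) |
| `pwm_min_score` | "85%" | — | matchPWM threshold for PWM family members |

# Numerical choices

* **Closed MID interval.** A value exactly on `mean ± t·sd` is MID. With
  discrete count data, boundary collisions are real, so the convention is
  load-bearing and tested.
* **Zero-norm vectors.** Cosine distance is undefined for all-zero rows,
  which short linkers produce routinely. The package fixes `D(0, y) = 1`
  for `y ≠ 0` and `D(0, 0) = 0`: zero rows cluster with each other and are
  maximally distant from everything else, keeping leave-one-out total and
  deterministic.
* **Distance canonicalization.** Nearest-neighbor decisions compare
  distances rounded to 12 decimals. Blocked BLAS matrix products and a
  scalar double loop can disagree in the last ulp on mathematically equal
  distances (duplicated or proportional count rows are common), which would
  otherwise let summation order decide ties. 12 decimals is far below any
  meaningful distance difference and far above double rounding noise; after
  canonicalization the blocked implementation is decision-identical to the
  naive double loop (tested on 200-sample instances, including zero rows).
* **Tie-breaks.** Equal distances go to the smallest training index; equal
  mRMR scores and equal relevances go to the smallest original column
  index; equal IFS accuracies go to the smallest prefix (parsimony).
* **Point-biserial = Pearson.** `r_pb` uses class sample proportions and
  the population (divisor n) standard deviation, which makes it exactly the
  Pearson correlation with 0/1-coded labels (asserted to 1e-12). A
  constant feature is an error, not a silent zero. p-values are kept at
  full precision internally; tables may round to 0.
* **Matrix file round-trip.** Values are written with 15 significant
  digits; read∘write reproduces labels exactly and values to ≥ 12
  significant digits.
* **`N` bases never match.** Under `fixed = "subject"` matching, pattern
  IUPAC codes are interpreted while subject letters are literal; the one
  leak (pattern `N` vs subject `N`) is closed by discarding hits that
  overlap an `N`. Conservative and deterministic.
* **Palindromes count twice.** A palindromic site matches once per strand;
  hits are identified by (strand, 5' position), and same-position
  same-strand matches of several members collapse to one. This dialect is
  documented because hit-count conventions differ between scanners.

# The synthetic world

`generate_matrix()` emulates the statistical skeleton of the real data:

* two classes with fixed 147-bp positive lengths and geometric-like
  negative lengths (`min 6 bp, mean ≈ 38 bp` — the short-linker scale
  deliberately exercises all-zero feature rows);
* per-family hit counts that are Poisson (optionally negative-binomial)
  with mean `rate × length`, divided by length;
* a configurable set of informative families with class-dependent rates.
  The default plants 9 of 35 families with cores depleted 2-fold relative
  to a background of 0.01 hits/bp (≈1.5 hits per core per family). The
  linker-enriched direction mirrors the biology the pipeline targets — TFs
  favor accessible linker DNA — and 0.01 hits/bp is a realistic per-family
  density for short degenerate fungal motifs.

`generate_genome()` plants non-overlapping 147-bp cores separated by
geometric gaps on random chromosomes and embeds concrete motif instances at
class-dependent densities, providing an end-to-end fixture for the interval
and scanning stages (the generator's own bookkeeping is the oracle:
`derive_linkers()` must return exactly the planted gaps).

**What the generator does not emulate:** the ~10-bp AA/TT rotational
periodicity of real core DNA, correlated motif co-occurrence, remodeler
effects, and mapping noise in core calls. A green synthetic test therefore
establishes the correctness of the computational pipeline and its
statistical behavior in a known world — not biological performance on real
chromatin data.

## A known limitation of the stated world

Length-normalized counts make even rate-matched "noise" features carry
class information: a feature value is `Poisson(rate·L)/L` with variance
`rate/L`, so short linkers produce spiky values (a single hit in a 10-bp
linker is 0.1/bp) while 147-bp cores produce smooth ones. Under the
three-state discretization this yields nonzero relevance for every feature,
and under cosine distance additional noise features keep improving the
jackknife accuracy instead of diluting it. Two observable consequences,
both reproduced by the test suite:

* the IFS curve in the default synthetic world saturates upward and places
  its vertex well above the number of planted families (the corresponding
  acceptance expectation is deliberately left failing rather than tuning
  the generator after measurement);
* "null model" tests that expect near-zero relevance must match the length
  models of the two classes (the package's null tests narrow the negative
  length distribution to ≈147 bp for exactly this reason).

On real data the same confound exists in principle — linkers *are* short —
and is part of what any length-normalized nucleosome/linker classifier
learns. Users comparing motif dialects or scanners should keep it in mind.

# Scope notes

The motif scanner is an explicit stand-in for commercial matrix-family
scanners: the pipeline needs per-family counts, not a particular scoring
engine, so count provenance is pluggable (IUPAC consensus by default, PWMs
with a `matchPWM` threshold for realism). No attempt is made to reproduce
proprietary matrix-family membership or similarity scores. Multiple-testing
correction is intentionally absent from the direction calls; k > 1 nearest
neighbors and non-cosine metrics are out of scope.
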