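---
title: "Modelling cell size patterning by endoreduplication timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell size patterning by endoreduplication timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepalsim)
```

## The biological question and the model

The outer epidermis of the *Arabidopsis* sepal mixes giant,
highly endoreduplicated pavement cells with much smaller diploid ones.
`sepalsim` implements the hypothesis that this pattern needs no
cell-type-specific growth control at all: if every cell grows at the
same relative rate, the only decision that matters is *when* a cell
stops dividing and starts endoreduplicating. A cell that switches at its
first opportunity keeps growing through three cell cycles without ever
halving, ending 16C and eight times the size of a cell that divided
throughout.

Concretely, each lineage founder emitted by a basal generative layer
has three **patterning cell cycles**. At the completion of cycle
k = 1, 2, 3 a 2C cell enters the endocycle with probability p_k
(irreversibly — committed cells never resume division) and otherwise
divides. After the third cycle, remaining 2C cells take one optional
extra division with probability `p_s`, a minimal stand-in for the
stomatal lineage; no guard-cell geometry or meristemoid behaviour is
modelled. Endocycles and mitotic cycles draw their durations from the
same distribution.

## The analytic branching model

Taking expectations over the decision tree gives the closed form used
for fitting (q_k = 1 − p_k):

* n16 = p1
* n8 = 2 q1 p2
* n4 = 4 q1 q2 p3
* n2 = 8 q1 q2 q3 · m(p_s, r)

with m the stomatal multiplier over r rounds. For the default single
round m = 1 + p_s. For r > 1 we use the recursion
m(r) = (1 − p_s) + 2 p_s · m(r − 1): a cell that *declines* its round
has decided its fate and terminates, rather than re-drawing in a later
round. The closed form is validated in the test suite against a
brute-force enumeration of every fate assignment of the tree.

`fit_probabilities()` inverts this map by box-constrained least squares
on fractions (deterministic multi-start `nlminb`), with a multinomial
likelihood available behind `objective = "multinomial"`. Least squares
is the default because the original objective used for the published
fit is not recoverable; both give identical interior solutions on exact
data. Partially observed fractions are supported deliberately: observed
4C pools endoreduplicated cells with mitotic G2 cells, so fitting on
(f16, f8) only, with p3 and p_s fixed, avoids that confound.
`bootstrap_fit()` adds percentile intervals under multinomial counting
noise at the reported nuclei count.

## Calibration of the wild-type scenario

Three published fractions pin down three parameters in closed form
(`calibrate_wildtype()`): 1.0% 16C and 5.5% 8C nuclei give p1 and p2;
the 29% guard-cell share gives p_s, since guard cells are exactly the
products of the stomatal division (two per dividing terminal 2C cell).
The third-cycle probability p3 is not identified by these data and is a
configured default, 0.8, consistent with the qualitative finding that
the endocycling probability rises from a low p1 to a high p3. The
result — p1 ≈ 0.049, p2 ≈ 0.143, p3 = 0.8, p_s ≈ 0.551, about 4.9
terminal cells per founder — reproduces that ordering automatically.

```{r calibration}
calibrate_wildtype()
expected_ploidy_fractions(calibrate_wildtype())
```

## The simulator

**Growth.** Area grows exponentially, doubling every
`doubling_time_hours` (default: the mean cycle time, 24 h), isotropically
in length and width. This is the simplest law under which the average
cell exactly doubles per cycle and longer cycles yield larger cells with
no extra mechanism. Terminated cells freeze; their recorded area is the
area at termination.

**Cycle times.** Durations are drawn per cell per cycle, by default
lognormal with mean 24 h and SD 9 h. These defaults are configuration,
not measured claims: live imaging shows small cells undergoing one to
four divisions in 72 h with cycle-time histograms at 6-h resolution, and
an empirical histogram (`cycle_time_distribution("empirical", ...)`,
optionally quantized to 6 h) can be supplied instead.

**Division.** Only transverse and longitudinal planes are allowed; the
plane is chosen to bring the even-split daughter aspect ratio closest to
2:1, measured as |log r − log 2|. The log metric is a deliberate choice
where the source rule is qualitative: the arithmetic distance |r − 2|
treats r = 1 and r = 4 asymmetrically, the log distance does not. Exact
ties (e.g. a 2:1 cell, where the candidates give r = 1 and r = 4) are
resolved by a fair coin from the seeded stream. The split fraction is
truncated-normal, N(0.5, 0.05) on [0.3, 0.7], giving the model's 10% SD
in daughter areas (the in vivo measurement is 8.5%; the asymmetry of
stomatal-lineage divisions is intentionally not reproduced — all
divisions, generative and stomatal included, use the same noise).

**Generative layer.** A fixed file of `generative_width = 8` columns;
each generative division is transverse, keeping one basal generative
daughter per column and emitting one apical founder. This is an explicit
oversimplification of the proliferative sepal base; no lateral widening
or mechanics is modelled, and cells carry only a column index and
rectangle geometry.

**Fate timing.** Fate is decided at cycle *completion*, so the decision
index k is the cycle just completed. The stomatal decision for a
terminal 2C daughter is made at its birth (the instant the lineage's
third cycle completes), and a declining cell terminates at its birth
area. This timing is what preserves the noise-free four-size limit: a
post-cycle decision would let terminal 2C cells double once more and
collide with the 4C size class.

**Scheduler and reproducibility.** A fixed step of `dt_hours = 0.5` h
grows all cells, then processes completions in ascending cell-id order,
consuming random draws in one documented order (fate; plane tie; split;
daughter durations; daughter stomatal decisions). A cycle completes at
the first step boundary at or past its sampled duration, so durations
are effectively rounded up to the step — exact for the synchronous and
6-h-quantized cases, and a sub-step perturbation otherwise. Identical
seed and configuration give bit-identical outputs. The run stops
founding new lineages once non-generative cells reach `target_cells`
(default 1,600, the wild-type epidermis count) and lets the rest finish.

```{r run}
run <- run_simulation(scenario_config("wildtype", seed = 1))
run
```

## Scenarios

`scenario_config()` bundles the mutant presets: `"lgo"` sets p1 = 0
(loss of the giant-cell pathway) with cycle times scaled to 0.8× the
wild-type mean, `"krp1"` sets p1 = 0.5 with 1.25× cycle times. The
scale factors are configuration defaults, not published values — the
published result is directional (shorter cycles in *lgo*, longer under
KRP1 overexpression, at 6-h imaging resolution). In all scenarios the
areal doubling time stays at the wild-type 24 h: the inhibitors alter
cycle timing and commitment probability, not growth rate, which is
exactly why *lgo* sizes shift down (more halvings per unit growth) and
KRP1 sizes shift up.

## Lineage statistics and the synthetic fixture

`generate_lineage_fixture()` emulates windowed live imaging of tracked
lineages: founders observed from birth, areas recorded every 6 h,
fates labelled divided / endoreduplicating / censored. It exists to test
the measurement utilities, and differs from real data in known ways: no
imaging noise or segmentation error, founders start exactly at birth,
and no spatial context.

`cycle_times_from_lineage()` measures a duration per internal edge
(first appearance of a cell to first appearance of its daughters) and
excludes censored cells and roots. Exclusion alone is biased in a
branching population: the boundary generation is about half of all
internal edges and is selected for short cycles (we measure ≈ 21 h mean
from a 24 h truth in a 72-h window). The `max_birth_h` argument
restricts measurement to cells born early enough that almost any cycle
completes in-window, which removes the selection (≈ 23.8 h recovered at
`max_birth_h = 24`); the raw, unguarded histogram is what imaging alone
would give.

`daughter_asymmetry()` reports sqrt(mean(d²)) of the relative deviation
d = 2a1/(a1+a2) − 1 at each division — the SD about the symmetric split,
invariant to which daughter is labelled first. Because both daughters
grow at the same relative rate, first-frame areas preserve the division
ratio exactly, and the statistic recovers twice the split-fraction SD.

`compare_area_distributions()` is a two-sample Kolmogorov–Smirnov test
on log2 areas. It stands in for the unavailable original statistical
comparison of model and in vivo size distributions and is documented as
such a substitution.

## Numerical choices and degenerate inputs

Areas at division are conserved exactly (the second daughter gets
`A - s*A`). Distinct-size counting clusters sorted areas at relative
tolerance 1e-6 — floating-point-safe for the noise-free limit, where
within-class areas agree to ~1e-13 but not exactly; for noisy runs the
count is reported but is not a biological quantity. Degenerate
configurations are handled explicitly: SD-zero distributions return
their mean exactly; `split_sd = 0` forces s = 0.5 without consuming
randomness; a fit with an observed fraction of exactly zero warns that
the corresponding parameter sits on the boundary; fits with more free
parameters than constraints are refused rather than silently
regularised.

## Problem sizes used in the checks

The packaged tests and the acceptance script use full-size runs
(~1,600-cell sepals) with 30 replicates where replicate means are
compared to published percentages, a 10,000-cell run for
simulator-versus-closed-form convergence (within three binomial
standard errors per class), 10,000 divisions for asymmetry recovery,
and fixtures of a few hundred lineages for the measurement utilities.
Unit tests use smaller targets (150–600 cells) chosen to exercise every
code path.

## Known limitations

* **No size homeostasis.** Cycles are timers, not sizers, and the
  generative layer inherits no size checkpoint, so log cell size
  random-walks across generative generations. Per-ploidy size
  distributions therefore broaden as development proceeds (CVs above 1
  at full run length), wider than real per-ploidy distributions. Means
  remain exact: each ploidy class stays a factor of two above the next
  in expectation.
* **Spatial pattern untested.** Cells carry a column index only; the
  model makes no claim about the spatial arrangement (clustering,
  spacing) of giant cells, and neighbour interactions are absent.
* **Stomatal lineage is a stub.** One optional symmetric-noise division
  with probability `p_s`; no meristemoids, no guard-cell pairing
  constraint, no highly asymmetric entry divisions.
* **Mechanics and geometry.** Rectangles with two division planes, no
  mechanical relaxation or curvature; terminated cells do not continue
  to expand (any apparent post-termination expansion in the source
  visualisations is a rendering artifact, not model behaviour).
* **Rare events excluded.** The occasional in vivo division of an
  endoreduplicating cell is not modelled; commitment is strictly
  irreversible here.
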