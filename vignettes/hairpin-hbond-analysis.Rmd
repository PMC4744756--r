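---
title: "Hydrogen-bond pattern analysis of beta-hairpin folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond pattern analysis of beta-hairpin folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinfold)
```

## The model

A beta-hairpin is held together by a small set of interstrand backbone
hydrogen bonds. For a two-strand hairpin with four such bonds (HB1..HB4),
every trajectory frame can be summarised by a 4-character fingerprint:
each bond is *closed* (`c`) when its geometry satisfies the detection
criteria, otherwise *open* (`o`). Four bonds span $2^4 = 16$ possible
patterns, from the fully unfolded `oooo` to the fully folded `cccc`.
The package estimates, from an MD trajectory (or any per-frame geometry
table), the empirical model over these patterns:

* **per-pattern populations** — the fraction of frames carrying each
  fingerprint;
* **per-pattern mean distances** — for each pattern, the mean
  hydrogen--acceptor distance of each bond over that pattern's frames,
  and their arithmetic mean across the four bonds;
* **folded classification** — a pattern is *folded* iff its mean
  hydrogen-bond distance is strictly below a threshold (3 Å by default);
  the *folding ratio* is the summed population of folded patterns;
* **population change map** — the row-normalised matrix of
  frame-to-frame pattern transitions, and from it the most probable
  folding pathway by a greedy walk.

### Detection criteria

A hydrogen bond is detected (closed) when the hydrogen--acceptor
distance is at most `distance_cutoff` (default 3 Å) **and** the
donor--hydrogen--acceptor angle is at least `angle_min` (default 120°).
Two conventions deserve a note:

* **Distance convention.** The distance is hydrogen-to-acceptor
  (H···A), not donor-to-acceptor. Closed backbone amide bonds then sit
  near 2.1--2.4 Å, which is the magnitude the per-pattern tables report;
  a donor--acceptor convention would shift all closed distances by
  roughly one N--H bond length and is not what the reported values
  reflect.
* **Boundaries.** Detection is inclusive at both boundaries (3.0 Å and
  120° count as closed). The folded rule, in contrast, is *strict*
  (`mean < 3.0`): a pattern whose mean distance is exactly 3.00 Å is
  unfolded. The reference tables contain exactly this boundary case, and
  only the strict rule reproduces its printed flag.

### Folding ratio modes

Two definitions are available. *Pattern-level* (default): classify each
pattern by its mean distances and sum folded-pattern populations — this
matches how the per-pattern table is constructed. *Frame-level*:
classify every frame by the mean of its own four distances and count
folded frames. They agree exactly when all frames of a pattern share one
geometry and differ slightly otherwise; both are always computed and
reported.

### Transition maps and pathway extraction

Transitions are counted between consecutive saved frames within a run;
pairs spanning run boundaries are never counted, because independent
production runs carry no dynamics across their junction. No lag-time
scan or Markov-state-model estimation is attempted — the map is a
descriptive summary at the trajectory's native frame stride.

The most probable folding pathway is the greedy walk from `oooo` to
`cccc` that follows, in each row of the map, the highest percentage
ignoring the diagonal. Two refinements make the walk well defined on
real maps:

* **Visited states are never re-entered.** The raw greedy rule can
  cycle (in typical maps, the partially folded states feed each other).
  The walk keeps a visited set and picks the best *unvisited* non-self
  destination; the second best is recorded as the alternative branch at
  every step.
* **Deterministic tie-breaks.** Equal percentages are resolved towards
  the destination with more closed bonds, then towards the
  lexicographically smaller label. This makes output reproducible, which
  the tests rely on.

If the walk exhausts its candidates before reaching the end state it
fails loudly, reporting the partial path, rather than returning a
misleading route.

## The synthetic generator

Because trajectories from microsecond MD are expensive and not shipped,
every stage is testable against a generator with analytic ground truth
(`markov_spec()`, `generate_pattern_chain()`, `emit_geometries()`):

* patterns evolve as a Markov chain over a chosen state set, with
  independent runs and a fixed seed (byte-identical regeneration);
* per-frame, per-bond geometries are drawn conditional on the pattern
  character: closed bonds from a normal distance (mean 2.2 Å, sd 0.2)
  and angle (mean 155°, sd 12°); open bonds from a normal distance
  (mean 6 Å, sd 1.5) and uniform angle (60--180°). These defaults mimic
  the magnitudes of backbone amide hydrogen-bond geometry and are
  otherwise arbitrary;
* each draw is rejection-resampled (capped at 1000 draws per value)
  until it classifies to the intended state, so classify-then-assign
  exactly recovers the generating pattern; an inconsistent
  criteria/emission combination fails with a configuration error
  instead of silently mislabelling.

The chain's analytic stationary distribution
(`stationary_distribution()`, the unit left eigenvector) predicts the
populations; the generating matrix predicts the transition map. The
test suite and acceptance script verify recovery on an 11-run, 5000
frames/run data set (55 000 frames — sized so the statistical checks
are sharp while the whole suite runs in seconds).

One statistical subtlety: frames of a Markov chain are autocorrelated,
so the naive iid binomial standard error understates the sampling
noise of a population estimate several-fold when diagonal entries are
large. Population-recovery checks therefore use three standard errors
where the SE is the empirical between-run SE (runs are independent),
floored by the binomial SE. Transition-map cells, by contrast, *are*
conditionally iid given the source-state visit count, so plain binomial
SEs apply there.

A packaged example chain (`inst/extdata/markov_ser3.yaml`) uses the
published transition map of the serine-bearing hairpin as its
generating matrix, rows renormalised to sum to one (the printed integer
rows sum to 94--100).

### What the generator does and does not emulate

It reproduces the statistical structure the analysis consumes:
pattern-conditional geometry distributions, Markovian pattern dynamics,
independent runs. It contains no physics — no force field, no solvent,
no correlation between bonds within a frame beyond the shared pattern,
and no within-state autocorrelation of geometry. Passing recovery tests
therefore demonstrates the *pipeline's* correctness, not that any MD
force field reproduces real folding ratios.

## Reference values and what is desk-checkable

Two published reference tables for a pair of closely related cyclic
hairpins (`ser3`, with a serine side chain that can form an extra
interstrand hydrogen bond, and `abu3`, its aminobutyric-acid variant
lacking it) ship as plain-text fixtures:

* the six-pattern population/distance table — the package reproduces
  every Average column entry to ±0.01 Å from the printed per-bond
  values (the table was evidently computed on unrounded data, so exact
  agreement to 2 decimals is not attainable from printed values alone)
  and every folded/unfolded flag exactly, including the mean-3.00
  boundary row;
* the two 6×6 population change maps — greedy extraction recovers the
  same pathway for both peptides,
  `oooo → oooc → cooc → cocc → cccc` (HB4 first, then HB1, then HB2/HB3),
  with per-step maxima equal to the printed cells.

The headline folding ratios of the original study (66% and 43%) derive
from 4.4 µs of MD per peptide and are not reproducible at the desk; the
top-6 tables imply 60% and 43% (the remainder sits in minor folded
patterns outside the printed six). The acceptance script reports the
implied ratios and the synthetic end-to-end ratio against its analytic
prediction instead of gating on cluster-scale numbers.

## Numerical and design choices

* **Units**: Å and degrees everywhere; 180° is a linear bond.
* **Rounding for reports**: populations to whole percent, distances to
  2 decimals, always half away from zero; internal computation is never
  rounded. Unpopulated patterns print population 0 and `NA` distance
  cells.
* **"Significantly populated"**: patterns whose rounded population is
  at least 1% (the `significant` column; report scope `top` keeps
  them, `full` prints all 16).
* **Atom identifiers**: `"RESNAME RESID ATOMNAME"`, matched exactly and
  case-insensitively; unresolvable or ambiguous identifiers are errors,
  never guesses.
* **Degenerate inputs**: empty series, non-stochastic matrices,
  reducible chains (no unique stationary distribution), all-zero
  transition rows and unreachable pathway ends all raise classed errors
  (`hairpin_config_error`, `hairpin_io_error`, `hairpin_compute_error`,
  ...) rather than propagating NaNs.
* **Trajectory input**: multi-model PDB is the required format; a file
  whose models disagree in atom count is rejected naming the offending
  frame. DCD (+ PDB topology) is supported as an optional binary
  reader. No fitting, alignment or periodic-boundary re-imaging is
  done — input molecules are assumed whole.

## A worked example

```{r example}
spec <- read_markov_spec(system.file("extdata", "markov_ser3.yaml",
                                     package = "hairpinfold"),
                         n_runs = 3, n_frames_per_run = 1500, seed = 23)
series <- emit_geometries(generate_pattern_chain(spec), seed = 23)
fit <- hairpin_fit(series)
summary(fit)
```

The populations track the stationary distribution of the generating
chain, the folded set here is `cccc` alone (with the default emission
means, a single open bond at ~6 Å pushes a pattern's mean above 3 Å),
and the extracted pathway is the canonical closing order.

```{r simulate}
sims <- simulate(fit, nsim = 2, seed = 1, n_frames = 10)
sims$run1
```

## Limitations

* The pipeline post-processes trajectories; it neither runs MD nor
  judges force fields. Pathways extracted from any one force field's
  map should be read with that caveat.
* The greedy pathway is a summary statistic of the one-step map, not a
  transition-path-theory flux; competing routes are only visible
  through the recorded alternative branches.
* Auxiliary-bond co-occurrence reports frequencies only; it deliberately
  implements no enrichment test.
* XTC input is not supported; convert to multi-model PDB or DCD first.
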