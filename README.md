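# hairpinfold

Hydrogen-bond pattern analysis of β-hairpin folding in molecular dynamics
trajectories.

β-hairpin peptides are a standard model system for early protein folding
and an increasingly common therapeutic scaffold. Their folded state is held
together by a handful of interstrand backbone hydrogen bonds, which makes an
intuitive reduced description possible: classify each of the four bonds
HB1..HB4 in every trajectory frame as open (`o`) or closed (`c`) and
summarise the frame by its 4-character fingerprint — `oooo` fully unfolded,
`cccc` fully folded, `2^4 = 16` patterns in all. This package implements
that analysis for anyone post-processing MD ensembles of hairpins
(or validating MD folding ratios against solution NMR ensembles).

Given a trajectory (multi-model PDB, optionally DCD) plus a hydrogen-bond
definition config — or a pre-extracted per-frame geometry table — the
package computes:

* **per-frame geometries** — hydrogen–acceptor distance *d* (Å) and
  donor–hydrogen–acceptor angle *θ* (degrees) for every defined bond;
* **detection** — bond closed iff *d* ≤ 3 Å and *θ* ≥ 120° (both
  inclusive, both configurable);
* **pattern table** — population of each of the 16 patterns, per-bond mean
  distances within each pattern, their arithmetic mean
  ⟨d⟩ = (d₁+d₂+d₃+d₄)/4, and the folded flag (folded iff ⟨d⟩ < 3 Å,
  strictly);
* **folding ratio** — summed population of folded patterns (pattern-level)
  or the fraction of frames whose own ⟨d⟩ < 3 Å (frame-level);
* **population change map** — row-normalised percentages of frame-to-frame
  pattern transitions (within runs only);
* **folding pathway** — the greedy walk `oooo → … → cccc` following each
  row's highest off-diagonal percentage, with deterministic tie-breaks and
  per-step alternative branches;
* **auxiliary-bond co-occurrence** — how often a declared side-chain
  hydrogen bond is closed overall and within each pattern.

A synthetic-trajectory generator (Markov chain over patterns + rejection-
sampled geometry emissions with analytic stationary distribution) provides
ground truth for every stage, so the full pipeline is testable without
running MD.

## Worked example

The packaged example Markov spec drives patterns with the published
transition map of a serine-bearing cyclic hairpin (rows renormalised):

```r
library(hairpinfold)

spec <- read_markov_spec(system.file("extdata", "markov_ser3.yaml",
                                     package = "hairpinfold"),
                         n_runs = 3, n_frames_per_run = 1500, seed = 23)
series <- emit_geometries(generate_pattern_chain(spec), seed = 23)
fit <- hairpin_fit(series)
fit
#> Hairpin H-bond pattern fit: 4500 frames in 3 run(s)
#> H-bond criteria: closed iff distance <= 3 A and angle >= 120 deg
#> Significant patterns (population >= 1%):
#>   cocc  47% (u)
#>   cooc  26% (u)
#>   cccc  10% (f)
#>   oooo   8% (u)
#>   ccoc   5% (u)
#>   oooc   4% (u)
#> Folding ratio (pattern-level): 9.7%

extract_pathway(fit$transition_map)
#> oooo -> oooc (5%) -> cooc (31%) -> cocc (13%) -> cccc (9%)
#>   step 2 alternative: oooc -> cocc (10%)
#>   step 3 alternative: cooc -> ccoc (8%)
#>   step 4 alternative: cocc -> ccoc (1%)
```

The populations recover the generating chain's stationary distribution
(cocc dominant at ~47%), and the extracted pathway is the canonical closing
order — HB4 first, then HB1, then HB2/HB3. With the default synthetic
emission means (closed 2.2 Å, open 6 Å) a single open bond pushes a
pattern's mean distance above 3 Å, so only `cccc` is folded here and the
folding ratio tracks its stationary probability (~10%); real hairpin data,
where open bonds in otherwise-closed patterns sit nearer 3.6–3.8 Å, also
classify `cocc`-like patterns as folded. `summary(fit)` prints the full
pattern table and transition map; `simulate(fit, ...)` resamples pattern
trajectories from the estimated chain; `plot(fit)` draws the map.

The same pipeline runs from the shell via
`inst/cli/hairpin-analysis.R` (subcommands `analyze`, `geometries`,
`patterns`, `transitions`, `pathway`, `simulate`), and `run_full_analysis()`
writes the complete, byte-stable report set (pattern table, folding
summary, transition map, pathway, JSON variant, provenance log).

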