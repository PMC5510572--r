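---
title: "Dating a founder allele from microsatellite haploblock decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a founder allele from microsatellite haploblock decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When the same rare disease allele is found in pedigrees with no known
relationship, two explanations compete: recurrent mutation at a fragile site,
or descent from a single founder. The ancestral haplotype around the allele
decides between them and, if descent is the answer, dates the founder. Every
meiosis gives recombination a chance to replace flanking material, so the
haploblock conserved across all carrier chromosomes shrinks, on the genetic
(centimorgan) scale, at a rate set by the total branch length of the carriers'
genealogy; microsatellites inside the block meanwhile accumulate stepwise
repeat mutations at a clock-like rate. A long conserved block with few
mutations means a recent ancestor.

`founderhap` implements this analysis for the motivating case of a 21-bp
in-frame duplication in *AIP* (chromosome 11q13.2) observed in nine unrelated
pedigrees, along with the two side analyses that complete the case: a
slipped-strand-mispairing analysis of the duplication itself, and one-phase
decay kinetics for the mutant protein's stability.

## Model and inference

### Observed summaries

Three numbers summarize the haplotype data:

* the number of carrier lineages `n` (one phased carrier chromosome per
  unrelated pedigree; 9 in the worked example);
* the genetic length of the conserved haploblock, reported as a measurement
  bracket `[low, high]` in cM. The bracket reflects marker resolution: `low`
  is the span between the outermost markers shared by all carriers, `high`
  the span extended to the nearest flanking discordant markers (1.83–2.59 cM
  in the worked example). The bracket is published once, without a per-map
  breakdown, so the package uses the same bracket for both genetic-map
  sources it models (HapMap and Rutgers);
* the number of within-block microsatellite mutations (exactly 1 in the
  worked example, a single deviating allele at D11S1249 on one chromosome).

### Haploblock decay on a genealogy

Given a carrier genealogy with most recent common ancestor (tMRCA) `t`
generations ago and total branch length `L`, recombination falls on every
branch as a Poisson process at 1 per Morgan per generation. A breakpoint on
*any* branch truncates the block conserved across all carriers, so the
distance from the disease locus to the block edge on each side is
exponential with rate `L` per Morgan, truncated at the ends of the typed
region. Typed markers whose genetic position falls inside the block count
towards the mutation opportunity: the within-block mutation count is Poisson
with mean `mu * L * (markers in block)`, with `mu` the per-locus
per-generation stepwise mutation rate (default `5e-4`, a typical
dinucleotide microsatellite rate; the published analysis does not state its
rate, so it is a configuration knob).

For the star genealogy (`demography_config("star")`), `L = n t` exactly, and
the one-sided block-survival probability has the closed form
`exp(-n t d)` at distance `d` Morgans — used throughout the tests as an
analytic cross-check of the simulation engine.

### The genealogy shape and its conditioning

The ABC conditions every simulated genealogy on its tMRCA: a candidate `t`
is drawn from the prior and the genealogy must have its root exactly there.
Exact conditioning by rejection is not possible for continuous event times,
so the engine draws coalescence times under the demography and rescales them
linearly so the root sits at `t`. Only the *shape* of the genealogy — the
ratio `L / t` — survives this rescaling, and the demography is therefore a
shape model, not a demographic-history claim. When the carrier pool shrinks
backward in time fast enough that the remaining coalescence hazard is
finite, each waiting time is drawn from its distribution conditioned on the
coalescence occurring (truncated-exponential inverse CDF), so draws always
fully coalesce.

The default shape is the constant-size Kingman coalescent
(`growth_rate = 0`; `present_size` then only scales the pre-rescaling times
and cancels). This choice was calibrated once against the worked example's
observed summaries: among the exponential-growth family, the constant-size
shape reproduces the published tMRCA median (47–48 generations) on the
published bracket, whereas strongly star-like shapes (large pools under
rapid growth) date the same data far too young, because a near-star
genealogy of nine lineages accumulates roughly `9 t` branch-length
generations and erodes the block several-fold faster than the data allow.
Scientifically, the Kingman shape encodes substantial recent coalescence
among the sampled chromosomes — consistent with the extensive "private"
haplotype sharing observed between subsets of the carrier chromosomes,
which is direct evidence that several of them are closely related within
the allele's genealogy.

### Rejection ABC

For each of `n_sims` simulations (default `2e5`): draw `t` uniformly from
the integer prior (default `1..300`), draw a conditioned genealogy shape,
simulate the block length and within-block mutation count, and accept when
the simulated block length falls inside the observed bracket (the bracket
itself is the acceptance window; `tol = 0` by default, treating the printed
range as the measurement interval) *and* the simulated mutation count
equals the observed count exactly (the analysis is conditioned on the
occurrence of the observed mutation). Accepted `t` values are the
posterior sample. Summaries are inclusive (Hazen) quantiles, weighted when
weights are present, so results are bit-reproducible and weighted and
unweighted summaries agree on uniform weights.

### Posterior adjustment and the carrier forecast

Older founders are overrepresented among *observable* alleles only if their
descendants multiplied enough to be sampled. `adjust_posterior()` reweights
each accepted `t` by the probability that a single founder leaves at least
`min_carriers` (default 9, the observed minimum number of unrelated
carriers per generation) present-day carriers under the forward branching
process. That probability is computed exactly by iterating the
branching-process probability mass function (truncated at 600; the
truncation is effectively absorbing for the tail probabilities used).

The forward model is a Poisson branching process: each carrier leaves
`Poisson(lambda)` carrier offspring per 25-year generation.
`estimate_current_carriers()` samples `t` from the adjusted posterior, runs
the process, rejects trajectories ending below `min_carriers` (rejection,
not importance weighting, mirroring the analysis being reproduced), and
summarizes accepted final-generation counts. The total alive today is the
per-generation median times the number of co-existing generations
(default 3), applied identically to the interval bounds.

`lambda` defaults to 1.02, calibrated jointly with the dating defaults: it
is consistent with mild long-run population growth per 25-year generation
and reproduces the published per-generation carrier median (32) from the
published observed summaries; 1.05, the other natural candidate, more than
doubles that median. The calibration was fixed once against the published
summaries and is not a fitting parameter of the package's tests.

### Key tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `mu` | 5e-4 | mutations / locus / generation | microsatellite stepwise rate |
| `prior_t` | 1..300 | generations | uniform tMRCA prior |
| `tol` | 0 | cM | widening of the acceptance bracket |
| `growth_rate` | 0 | per generation | genealogy shape (0 = Kingman) |
| `lambda` | 1.02 | offspring / carrier / generation | forward growth factor |
| `min_carriers` | 9 | carriers | rejection floor = observed minimum |
| `coexisting_generations` | 3 | generations | total-alive multiplier |
| `generation_time` | 25 | years | generations-to-years conversion |

## The synthetic-data generator

`simulate_str_haplotypes()` emulates the study conditions: 14 microsatellite
loci spanning 8.3 Mbp around the disease locus (the bundled map is
synthetic — the published analysis names only D11S1249 of its markers and no
coordinates — but embeds the published block geometry: the markers
bracketing the core block lie 2.79 Mbp / 1.83 cM apart, the flanking
markers 3.63 Mbp / 2.59 cM), carrier chromosomes descending from one
founder through a genealogy drawn by `simulate_genealogy()`, recombination
as a Poisson process on the cM scale along every branch, stepwise ±1-repeat
mutations at rate `mu`, and background chromosomes drawn per locus from
categorical allele distributions (default: discretized normal over founder
± 4 repeats, giving a realistic ~20% identity-by-state match to the founder
allele).

Simplifications, stated so that passing tests are read correctly:

* background alleles are in linkage equilibrium (drawn independently per
  locus), and each tip's off-segment alleles are drawn independently — two
  tips that inherit the same post-recombination background are not forced
  to match, so "private sharing" beyond the founder segment arises only by
  chance;
* mutations are simulated on the retained founder segment; mutations on
  background stretches are absorbed into the background draw;
* panels are emitted phased (the study's haplotypes were statistically
  phased upstream; phasing is out of scope, though `unphase_panel()`
  exports diploid-style unordered genotypes for format realism);
* chance identity-by-state can extend a detected block past a true
  breakpoint, so detected spans are upward-biased by roughly one marker
  interval — one reason the detector reports a min/max bracket rather than
  a point length.

Because the generator and the ABC share the genealogy and decay models,
parameter-recovery experiments (95% credible intervals covering the true
`t` in about 95% of synthetic panels) validate the inference machinery, not
the realism of any demographic assumption.

## Numerical and design choices

* **Block detection** is exhaustive over contiguous marker windows
  containing the anchor (the marker nearest the disease locus by default):
  maximal locus count wins, ties broken by greater genetic length, then
  leftmost — deterministic. Identity is identical-by-state on integer
  repeat numbers; a window may contain up to `max_mutation_loci` (default
  1) markers at which exactly one chromosome deviates, recorded as
  within-block mutations. With only two carriers a disagreement is
  irreconcilable (no majority allele), and an anchor that is itself
  irreconcilable is an input error.
* **Span conventions**: `span_min` is the distance between the block's
  outermost markers; `span_max` extends to the nearest flanking discordant
  markers or the region ends. Physical spans are differences of marker
  positions; genetic spans are differences of map positions.
* **Tandem-duplication placement** is ambiguous when the duplicated segment
  abuts a repeat; the canonical placement is the 3'-most tandem square
  (the HGVS convention for duplications), with all equivalent placements
  listed. The direct-repeat search maximizes repeat length first, then
  mismatch count; in homopolymer contexts a longer imperfect repeat
  therefore outranks a shorter perfect one.
* **Decay fits** use bounded Levenberg-Marquardt (`minpack.lm::nlsLM`) on
  `level(t) = (100 - plateau) exp(-K t) + plateau` with plateau in
  `[0, 100]`, deterministic initialization (plateau from the smallest
  observed level, `K` from a log-linear regression of plateau-subtracted
  levels), and replicates pooled, not averaged, so residual degrees of
  freedom count every point. A perfectly flat curve has no decay signal
  and returns `K = 0` by convention. The extra sum-of-squares F test
  compares the pooled shared fit against per-construct fits with
  `F = ((SSE_sh - SSE_sep) / 2) / (SSE_sep / (n - 4))`.
* **Reproducibility**: every stochastic function takes a seed; the pipeline
  derives per-stage streams from one master seed, and artifacts embed the
  configuration hash and seed. Identical configuration and seed give
  byte-identical outputs.

## Problem sizes

The package's own test suite runs the ABC at `2e5` simulations for the
worked example (posterior of roughly 1500 accepted draws), 200 replicates
at `2e4` simulations each for the coverage experiment, 1000 null
replicates for the F-test size check, and 100 seeds for the
stability-ordering check; these sizes give Monte-Carlo error comfortably
inside the tolerances they are tested at while keeping the whole suite in
a few minutes on one core. The acceptance script uses the same `2e5` / `1e4`
sizes as the worked example.

## Worked example

```{r example}
library(founderhap)

post <- abc_tmrca(aip_observed_summary("hapmap"), abc_config(seed = 1))
post
adjusted <- adjust_posterior(post)
carriers <- estimate_current_carriers(adjusted, forward_config(seed = 2))
carriers
total_alive(carriers)

seqs <- aip_duplication_sequences()
event <- find_tandem_duplication(seqs$wt, seqs$mut, cds_offset = seqs$cds_offset)
find_direct_repeats(event)

summarize_onset(aip_cohort())
```

## Limitations

* The published analysis does not state its simulator's demographic
  parameters, mutation rate, or prior; the calibrated defaults here are
  *a* parameterization under which the published observed summaries
  reproduce the published medians, not a reconstruction of the original
  settings. Posterior intervals are accordingly somewhat wider than the
  published ones.
* The Rutgers-map observed block length was not published separately; both
  map sources share one bracket, and the bundled Rutgers map column is
  synthetic.
* No gene conversion, migration, interference, or sex-specific maps; the
  recombination model is a homogeneous Poisson process on the cM scale.
* The carrier forecast has no age or pedigree structure: "three co-existing
  generations" is an arithmetic multiplier, matching the analysis being
  reproduced.
* Real decay time courses and replicate counts were not published;
  stability-kinetics correctness is established by exact recovery on
  noiseless data, simulation-based recovery, and the F test's type-I error
  calibration.
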