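---
title: "Simulation model and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation model and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfgrid)
```

# The model

`wfgrid` is a forward-time Wright–Fisher simulator for populations arranged
on a rectangular grid. Populations are hermaphroditic, randomly mating,
haploid or diploid, with non-overlapping generations. Every generation each
cell passes through an ordered cycle of phases:

1. **Extinction.** Each occupied cell is emptied with its per-cell
   probability $e$. Emptied cells stay on the map and can be recolonised.
2. **Migration.** Rates are the probability that each individual migrates in
   a generation: the emigrant count from a cell of size $N$ is
   $\mathrm{Binomial}(N, m)$. Destinations are either a uniformly chosen
   in-grid 4-neighbour (von Neumann adjacency, no wraparound) or follow an
   explicit per-ordered-pair rate matrix. All emigrant draws use
   pre-migration sizes and arrivals are applied afterwards, so the update is
   synchronous and order-independent across cells. Migrants reaching an
   empty cell found a new population — together with extinction this gives
   stochastic turnover of occupancy.
3. **Mutation.** Under the infinitely-many-sites model the number of new
   mutations in a cell is $\mathrm{Poisson}(\lambda)$ with
   $\lambda = \mu g N$, where $\mu$ is the per-site rate, $g$ the genome
   length in base pairs and $N$ the number of individuals (a configuration
   switch rescales to gene copies). Each mutation occupies a uniformly drawn,
   previously unused position and starts as a single derived copy in a
   uniformly drawn carrier.
4. **Selection assignment.** A new allele's coefficient $s$ is 0 (neutral),
   a fixed value, or a $\mathrm{Gamma}(k,\theta)$ draw, optionally negated
   for deleterious regimes (draws $\le -1$ are rejected, at most 100 times).
   A per-cell multiplier makes coefficients spatially variable; scheduled
   events make the multiplier (and migration, extinction, sizes) temporally
   variable.
5. **Growth.** The growth rate $r$ is drawn per cell per generation from
   $\mathrm{Normal}(\bar r, \sigma^2_r)$ and the target size is
   $$N_t = \operatorname{round}\!\Big(N_{t-1} + r\,N_{t-1}\Big(1 -
   \frac{N_{t-1}}{K}\Big)\,a\Big),\qquad
   a = \begin{cases}(N_{t-1}-A)/K & A \text{ set}\\ 1 &
   \text{otherwise,}\end{cases}$$
   clamped at zero, with round-half-to-even. $K$ is the carrying capacity
   and $A$ the Allee threshold: below $A$ the growth increment turns
   negative and small populations decline. A scheduled `step_size_change`
   event overrides the computed target (instantaneous size change). We use
   this increment form deliberately: a literal replacement form
   $N_t = rN_{t-1}(1-N_{t-1})/K\cdot(N_{t-1}-A)/K$ collapses any population
   with small $r$ and cannot describe logistic growth toward $K$.
6. **Reproduction.** Wright–Fisher resampling to the target size: each
   offspring draws its parent(s) independently with probability
   proportional to fitness (two draws for diploids, selfing allowed), and at
   every site independently receives one uniformly chosen allele copy from
   each parent. Sites are completely unlinked — there is no recombination
   map and no linkage. Fitness is multiplicative over sites with genotype
   weights $1$, $1+hs$, $1+s$ (haploid: $1$, $1+s$); the dominance
   coefficient defaults to $h = 0.5$ because the upstream literature for
   this class of simulators leaves dominance unspecified and semidominance
   makes the diffusion benchmarks (below) exact.

After reproduction, sites lost everywhere are dropped and sites fixed in
every occupied cell are moved to a fixed-site registry (their genotype
columns are removed; exports can optionally re-include them as monomorphic
loci).

## Genotype storage

Because sites are unlinked, the per-copy phase of a genotype carries no
information: transmission probabilities and fitness depend only on the
per-site dosage. Genotypes are therefore stored as an individuals × sites
integer dosage matrix (0..ploidy) rather than a three-dimensional per-copy
array. This is a lossless statistical reduction, and the unphased GENEPOP /
PLINK / Geneland exports are unaffected.

## Randomness and reproducibility

One master seed feeds eight named L'Ecuyer-CMRG streams (initialisation and
one per phase, plus export subsampling), derived with
`parallel::nextRNGStream()`. Extra draws in one phase therefore never
perturb another phase's sequence. The stream states travel inside the grid
object and serialise losslessly into checkpoints, so identical
(configuration, seed) pairs yield byte-identical checkpoints and a resumed
run continues the exact trajectory of an uninterrupted one.

## Temporal variability

Two mechanisms: an in-run event schedule (`step_size_change`,
`set_extinction_prob`, `set_migration`, `set_selection_multiplier`, per cell
or grid-wide, taking effect at the start of their generation), and chained
runs through checkpoints, where a new configuration may change any
parameter except the structural ones (grid dimensions, ploidy, genome
length) unless explicitly permitted.

# Parameters that matter

| parameter | meaning | default |
|---|---|---|
| `mutation_rate` ($\mu$) | per site per generation | — (required) |
| `genome_length` ($g$) | base pairs; $\lambda = \mu g N$ | — (required) |
| `migration_rate` ($m$) | per-individual emigration probability | 0 |
| `carrying_capacity` ($K$) | logistic equilibrium size | initial size |
| `growth_rate_mean/var` | distribution of $r$ | 0, 0 |
| `allee` ($A$) | decline threshold, $A < K$ | disabled |
| `extinction_prob` ($e$) | per cell per generation | 0 |
| `dominance_h` | heterozygote weight $1 + hs$ | 0.5 |

With `growth_rate_mean = 0` nothing regulates sizes: under migration the
per-cell sizes then perform a conserved-sum random walk. Island-model
comparisons (below) therefore use a strong deterministic logistic pull
(`growth_rate_mean = 1, growth_rate_var = 0`) to hold demes at $K$.

# What the validation suites show — and what they do not

The accuracy programme compares simulated behaviour against classical
closed-form expectations (`validate_suite()`):

* **Mechanism means.** Emigrant counts are $\mathrm{Binomial}(N, m)$
  (mean $Nm$); mutation counts are $\mathrm{Poisson}(\mu g N)$ (variance
  equal to the mean). Both are measured by re-executing the phase thousands
  of times from a fixed state while carrying the phase stream forward.
* **Neutral fixation.** A single new mutation fixes with probability
  $1/(2N)$ (haploid: $1/N$).
* **Selected fixation.** Kimura's diffusion result
  $(1-e^{-2s})/(1-e^{-4Ns})$, in which $s$ is the heterozygote advantage
  under additive selection (genotype fitnesses $1, 1+s, 1+2s$) — in the
  engine's $1/1+hs'/1+s'$ weights, $s' = 2s$ with $h = 0.5$.
* **Heterozygosity decay.** $H_t = H_0 (1 - 1/(2N))^t$ from $p_0 = 0.5$.
* **Equilibrium $F_{ST}$.** Two demes exchanging migrants, compared with
  the finite-island expectation $1/(1 + 4Nm\,(d/(d-1))^2)$, $d = 2$.

The fixation and decay suites run on single-locus genotype-count samplers
(`wf_fixation_replicates()`, `wf_drift_replicates()`) that implement the
exact marginal law of the engine's reproduction phase for one unlinked
site: offspring alleles are i.i.d. Bernoulli with the fitness-weighted
transmission probability
$p^\* = (\tfrac12 n_1 w_1 + n_2 w_2)/\sum_g n_g w_g$, so genotype counts
are multinomial. Tracking counts instead of individuals lets 20,000
replicates run as vector operations; a distributional test in the suite
verifies that `apply_reproduction()` reproduces this law's mean and
variance, and a reduced-scale full-engine experiment (800 replicates,
$N = 20$) independently recovers $1/(2N)$. These suites validate the
reproduction and selection machinery, not the spatial machinery; the
$F_{ST}$ suite covers migration with the full engine.

## Design of the $F_{ST}$ experiment

Two demes of $N = 200$ diploids run to mutation–drift–migration balance at
$Nm \in \{0.25, 1, 4\}$. After a burn-in covering the slower of the
coalescent ($2N$) and migration ($1/m$) timescales, the sites × demes
frequency matrix is sampled every 30 generations for 1600 generations, in
10 independent replicate runs; $\sum H_T$ and $\sum \bar H_S$ are pooled
over sites, time points and runs before taking the single ratio
$F_{ST} = (\sum H_T - \sum \bar H_S)/\sum H_T$ (a ratio of sums is far less
variable than averaged per-site ratios), with a jackknife over runs for the
standard error.

Two deliberate choices deserve note:

* **Mutation influx.** Under infinite sites $E[\pi]$ is linear in the
  per-copy mutation rate, so the pooled ratio is insensitive to it in
  expectation; the influx (0.5 new mutations per deme per generation) is
  chosen purely to supply enough segregating sites per sample. The exact
  two-deme recursion with mutation, `theory_two_deme_gst()`, is provided to
  quantify the residual identity-based shift.
* **Binomial migrant counts.** Because whole individuals migrate in
  binomially distributed numbers, lineages co-migrate in correlated clumps,
  which measurably raises equilibrium $F_{ST}$ above the
  independent-lineage island prediction; the excess shrinks roughly
  inversely with deme size at fixed $Nm$ (about +45% at $N = 50$, +10% at
  $N = 200$ for $Nm = 4$, reproduced independently by a frequency-level
  simulation with hypergeometric allele transfer). $N = 200$ keeps this
  model-intrinsic excess inside the comparison tolerance while remaining
  cheap enough for replicated runs. This is a real property of
  individual-based binomial migration, not an artefact.

## What the synthetic conditions do not show

The generators emulate idealised conditions — constant regulated sizes,
symmetric migration, free recombination, no selection except where stated.
Passing these suites shows the stochastic machinery is correct at the
distribution level; it does not certify behaviour for linked loci (not
modelled), strongly fluctuating demography, or non-equilibrium range
expansions, although those regimes are exactly what the simulator is for.

# Numerical choices and degenerate inputs

* Growth targets use round-half-to-even and clamp at zero; a zero target
  empties the cell.
* Gamma selection draws $\le -1$ are redrawn at most 100 times, then error;
  fitness $\le 0$ after spatial multipliers is a hard error naming the
  locus position.
* A genome with every position already mutated raises an error rather than
  violating the infinite-sites invariant (unreachable at realistic scales).
* A fully extinct grid terminates the run early with status `"extinct"`;
  migrants can only come from occupied cells, so no recovery is possible.
* Grid coordinates are (row, col), 1-based in configurations and output
  files, 0-based only internally; site positions are 0-based half-open
  internally and 1-based in every output file.
* Initial states: empty (no segregating sites), a user SNP list with
  per-site frequencies (genotypes drawn binomially per gene copy), or a
  checkpoint. These three cover mutation-free starts, standing-variation
  starts and restarts.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script replicate counts (10,000 migration
phase executions; $10^6$ mutation draws; 20,000 fixation replicates at
$N = 50$ and $N = 500$; 2,000 drift trajectories over 200 generations;
10 × 3,000-generation two-deme runs per $Nm$ setting) were chosen so the
Monte Carlo standard errors sit well inside each comparison's stated
tolerance; they complete on a single CPU in minutes.

# Known limitations

* No linkage or recombination map; no sequence evolution beyond biallelic
  SNPs; no separate sexes or selfing prohibition; no continuous space.
* Selection acts through fertility (fitness-proportional parent sampling),
  not viability; with very strong selection and tiny populations the two
  differ.
* The Allee term follows the increment form above; other parameterisations
  of depensation exist.
* `set_migration` events currently target the adjacent-uniform mode; in
  explicit-matrix mode temporal changes go through chained checkpointed
  runs.
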