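---
title: "Stochastic simulation of crop breeding programs with breedsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic simulation of crop breeding programs with breedsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsim)
```

# The model

breedsim simulates breeding programs for self- and cross-pollinated crops at
the level of individual plants and individual loci, forward in time. A run
has four stages: a genetic model is specified; a founder population is
simulated (or imported) to create linkage disequilibrium; the selected
population is bred through overlapping cycles of phenotyping, selection and
seed propagation; and per-time-step summaries are recorded and aggregated
over replicates.

## Genome and founder population

The genome is a set of chromosomes with selectable loci (bi-allelic QTLs and
markers) at evenly spaced map positions in Morgan, plus equidistant neutral
IBD-tracer loci used only to measure realized inbreeding. Meiosis draws the
number of crossovers per chromosome from a Poisson distribution with mean
equal to the map length, places breakpoints uniformly, and switches strands
at each breakpoint — no interference, no sex differences. A breakpoint
falling exactly on a locus (an event of measure zero on a continuous map)
assigns the locus to the left segment; the tie-break only matters for
reproducibility of a given seed.

Founder linkage disequilibrium is built by a Fisher-Wright process from a
monomorphic wild-type start: discrete generations of random mating without
selfing (sires and dams from disjoint pools, re-split at random each
generation), recurrent bi-allelic mutation (an allele toggle with a
per-locus, per-gamete probability), drift through finite size, and weak
directional selection that culls the 5% of offspring with lowest TBV and
replaces them with freshly drawn matings (replacements are not re-culled, so
the generation size is restored deterministically). Mutation operates in the
founder phase only; the breeding phase is mutation-free by default.
Expansion and contraction of the founder population are available through a
per-generation size schedule; no default shape is imposed.

QTL effects for a single trait are exponential in magnitude (rate 1 — the
scale is immaterial after standardization) and negative with probability
0.9, mimicking mostly deleterious mutants; the wild-type effect is 0.
Multi-trait architectures draw each QTL's effect vector from a multivariate
normal with the user's genetic covariance, so correlated traits share one
set of QTLs.

## Variance standardization and the plot-heritability calibration

A plant's TBV is the effect-weighted sum of its mutant-allele dosages.
Effects are rescaled by one scalar per trait so that the realized variance
of an *outbred* (Hardy-Weinberg) base cohort equals the target genetic
variance exactly. Realized variance was chosen over the expected
`2*sum(p*q*a^2)` because it is exactly testable and makes the base cohort
the unit of account. The genetic variance parameter therefore refers to the
outbred base; fully inbred lines sampled from the same pool carry twice
that variance between lines. This convention is what makes the
plot-heritability closed form self-consistent:

    sigma_e2 = 2 * Ns * H * sigma_g2 * (1 - h2_plot) / h2_plot
               - (1 - H) * sigma_g2

where `Ns` is the number of plants per plot and `H` the homozygosity
frequency of the generation. The parse treats the between-line genetic
variance `2*H*sigma_g2` as signal and the within-line variance
`(1-H)*sigma_g2` as part of the plot residual; at `H = 1` it reduces to the
fully inbred form `2*Ns*sigma_g2*(1-h2)/h2`, and simulating unselected
inbred line-plots with the calibrated residual then realizes the target
plot heritability (defined, throughout, as the squared correlation between
the plot sum of TBVs and the plot sum of phenotypes). Because the printed
form of this equation is typographically ambiguous in the wider literature,
the parse above is stated explicitly and covered by a Monte-Carlo test.
The engine computes `H` as the realized mean homozygosity of the cohort
being phenotyped; an override for the selfing-generation expectation
`1 - (1/2)^t` is available by passing `H` directly. Under selection the
closed form is only a starting point, and
`calibrate_residual_variance_empirical()` implements the multiplicative
trial-and-error loop (tolerance 0.01, at most 20 iterations).

Phenotypes are `y = g + e` with independent Gaussian residuals — no spatial
field structure and no common-plot environmental term. Plot values are
*sums* (not means) of member phenotypes, matching the heritability
definition above. An infinitesimal alternative (base TBVs normal,
offspring = midparent + Mendelian-sampling deviation shrunk by parental
inbreeding) is provided at function level for polygenic studies.

## Relationship matrices, BLUP and GBLUP

Pedigree inbreeding and the numerator relationship matrix use the tabular
recursion (`a_ii = 1 + F_i`, `F_i = a_sd/2`); doubled haploids are set
`F = 1` with their single progenitor recorded as both parents. The genomic
relationship matrix is VanRaden's method 1 over the *marker* loci only
(QTLs are unknown to the in-silico breeder), centered with base-population
allele frequencies frozen at base sampling; monomorphic loci are excluded.

Breeding values solve the standard mixed-model equations with one overall
mean per trait as the only fixed effect and user-supplied (here: true)
variance components; REML estimation is out of scope. Multi-trait systems
are supported through the Kronecker structure of the genetic covariance.
Repeated plot records of a line enter as repeated records of one genetic
effect; no permanent-environment term is fitted. A singular or
near-singular relationship matrix is blended (`0.99*K + 0.01*I`, with a
message) before re-solving — this arises naturally when nearly fixed inbred
lines have almost identical marker rows, and it is why a genotype-clone of
a reference plant receives a *nearly* (not exactly) identical GEBV.

Optimum-contribution selection maximizes `c'a - (omega/L^2) (c+Pv)'A(c+Pv)`
over the simplex (`c >= 0`, `1'c = 1`; plants are treated as one
hermaphroditic pool). The penalty placement follows penalty-form OCS with
the generation interval defaulting to `L = 1`, so the user-facing knob is
effectively `omega`. The solver is projected-gradient ascent with a
deterministic uniform start, a step from the Lipschitz constant of the
gradient and convergence tolerance 1e-8; `omega = 0` is handled exactly
(the linear objective concentrates on the best candidate). Contributions
become integer mating counts by largest-remainder apportionment.

## The breeding-program engine

A plan defines, per generation of an n-generation cycle, the phenotyping
(trait, plots, plants per plot), the selection rule (unit, criterion,
number kept), germplasm storage, and the propagation (selfing, crossing,
cloning or DH; seed counts resolved per plant, family or line according to
the selection unit). A calendar maps generations to time-step offsets; a
new cycle starts at every time step, so at steady state one cycle is active
per distinct offset. Speed breeding compresses the early generations into
one offset, and compressed stages execute back-to-back in generation order
within a time step. The first cycles source parents from the founder pool;
later cycles draw them from stored germplasm. The germplasm available at a
given time is the most recently stored material of the eligible
generations (at time t, the lines now standing at F5/F6/F7 are those stored
at t-1); parents are drawn uniformly without replacement from that pool by
default, or by truncation on the stored selection criterion. Uniform is the
default because stored entries are already selected material.

## The shipped wheat plans

`wheat_plan()` builds the three 8-generation winter-wheat plans: PS
(phenotypic line breeding), GS (identical 10-year burn-in, then GBLUP line
selection at F5-F7 with an F4 reference population growing by one cohort
per year) and SPB (as GS with F1-F4 compressed into the first year, so 5
rather than 8 cycles overlap and 5 rather than 7 cycles are founder-
sourced). Three correlated traits are simulated: breeder's visual
preference (BVP, individual heritability 0.1, used for within-family
selection at F2 and F4), preliminary-trial yield (YP, plot heritability
0.2, family selection at F3 and line selection at F5) and advanced-trial
yield (YA, plot heritability 0.3, line selection at F6/F7 and the reported
gain trait), each with genetic variance 1 in standardized units and a
configurable YP-YA correlation (default 0.3).

Full scale (`scale = 1`) follows the published program: 20 parents, 50 of
190 possible crosses, 50 F1, 500 F2 (within-family 5 of 10 on BVP), 7500
F3 (family selection 45 of 50 on three YP plots), 2700 F4 (within-family 5,
giving 225 single-seed-descent lines), 4500 F5 (one 20-plant YP plot per
line, 75 lines kept), then 900 seeds per line with nine plots at F6
(30 kept) and F7 (5 kept), and 5 released F8 lines; germplasm is stored at
F5/F6/F7. One deliberate correction: the stated cap of 4 crosses per parent
cannot produce 50 distinct pairs among 20 parents (50 pairs need 100
parent-uses, the cap allows 80), so the full-scale plan uses the minimal
feasible cap of 5; `enumerate_crosses()` itself enforces the cap and
reports the infeasibility bound.

In the GS stages the engine appends the current line-mean records to the
reference before solving, uses single-trait GBLUP on the advanced-yield
(YA) reference for ranking, and supplies the record residual variance
`sigma_e2(stage)/(n_plots*Ns)` (line means; the small within-line
Mendelian-sampling variance of nearly fixed lines is ignored). The YP line
means are stored in the reference as well, but a joint multivariate
YP+YA evaluation is not run inside the engine — doubling the unknowns at
every stage for a correlation of 0.3 buys little ranking accuracy; the
multi-trait solver is available directly through `estimate_ebv_gblup()`.

## Reduced test scale

`scale = 5` divides the funnels by five while preserving the within-family
structure: 10 parents, 10 crosses (cap 4), 100 F2, 1500 F3 (9 of 10
families), 540 F4 (45 lines), 900 F5 (15 lines kept), 180 seeds per line
in nine 20-plant plots, 6 then 1 line kept, 180 F8 of one released line.
Parents are halved rather than divided by five because 10 crosses under a
usage cap need at least 5 parents and the germplasm store must cover the
parent draw with a margin.

The default reduced-scale genome is one 3-Morgan chromosome with 500 loci
(every 10th a QTL, i.e. 50 QTLs; an explicit QTL index list supports
random designations such as 1039 of 9582) and 20 IBD tracers; the founder
phase runs 500 plants for 400 generations at a per-locus mutation rate of
0.0025 (`theta = 4*N*mu = 5`). These values were chosen against an a-priori
validity requirement for a down-scaled program: the miniature must remain
in the qualitative regime of the full program, with genetic variance still
segregating and all three plans showing measurable gain at the 25-year
horizon. A one-Morgan map with a thin founder pool fails that requirement —
hitch-hiking and the small parent funnel drive the speed-breeding program
to complete fixation (variance exactly zero, identical releases) by
mid-horizon, and leave the phenotypic program's rate of gain statistically
indistinguishable from zero; neither degeneracy appears at full scale. The
3-Morgan, theta = 5 miniature keeps the phenotypic and genomic plans
segregating to the horizon (the speed-breeding plan still approaches
fixation in its final years — the one distortion of the miniature that
scale alone cannot remove, noted under limitations) while staying a
single-chromosome stand-in for a multi-chromosome cereal map of a few tens
of Morgan and a commercial founder panel.

Two residual distortions of the miniature are worth understanding before
reading its outputs. First, the phenotypic plan's release series (the
yearly mean TBV of the released F8 line) barely trends over the late
window even though its F4 candidate means creep upward: the released line
sits at the population mean *plus* a selection uplift proportional to the
between-line standard deviation, and as variance erodes that uplift
shrinks at about the rate the mean grows. Fold comparisons that divide by
the phenotypic plan's late-window slope are therefore ill-conditioned at
this scale. Second, the speed-breeding plan realizes its advantage early —
its level is the highest of the three plans through most of the horizon —
but its faster elite turnover also exhausts variance sooner, so its
*slope* over the last 15 years can fall below the genomic plan's even
while its *level* stays ahead. Both effects vanish at full scale, where
variance survives the horizon.

# What the generator does and does not emulate

The synthetic founder reproduces drift-mutation-selection equilibrium LD,
allele-frequency spectra with mostly deleterious mutants, and the funnel
structure of a commercial line program. It does not emulate: real wheat
marker ascertainment or LD decay profiles (a real panel can be supplied via
the phased-genotype importers), genotype-by-environment structure beyond
the correlated-trait device, dominance or epistasis, variable recombination
or interference, or spatial field effects. Passing tests therefore show
internal consistency of the model and orderings that are robust to the
miniature's scale — not calibrated absolute gains for any real program.

# Numerical choices and degenerate inputs

* Ties in truncation selection break by ascending plant id; runs are
  bit-reproducible for a fixed seed (one R RNG stream drives R and C++
  code; replicate r of an experiment uses `base_seed + r`).
* Cross sets are drawn pair-by-pair among cap-feasible candidates with
  whole-set redraws on dead ends (1000 attempts), then a deterministic
  greedy usage-balanced fill with a message.
* Variances are reported with the n-1 denominator; the within/between
  family split is exact (`total = within + between` at every record).
* A monomorphic founder pool is a warning, not an error; a zero-variance
  selection criterion yields an undefined (NA) accuracy with a message;
  an infeasible plot-heritability target reports the attainable bound.
* Standardization requires at least one segregating QTL; it errors on a
  zero-variance base cohort.

# Problem sizes used in the tests

The structural acceptance run executes the full-scale phenotypic plan (one
complete cycle plus its overlaps, about 3.5e5 plants) on a deliberately
small 60-locus genome, since the bookkeeping is independent of the genetic
architecture. The plan-comparison study runs the three reduced-scale plans
on 10 paired founder replicates over 25 years — about 1.3e5 plants and a
few hundred GBLUP solves per replicate — and summarizes OLS gain slopes of
the released generation over years 11-25. Monte-Carlo checks use 1e4-1e5
draws. These sizes keep the full suite in the tens of minutes on one core
while leaving the stochastic tolerances (binomial or slope-sampling error)
well inside the asserted bounds.

# Known limitations

* Single-step GBLUP, Bayesian whole-genome regression and REML variance
  estimation are out of scope; the in-silico breeder is given the true
  variance components.
* The engine's GS stages are single-trait; multivariate evaluation exists
  only at the function level.
* OCS and threshold selection are available as selection-module functions
  but are not wired into the three shipped plans (which, like the programs
  they model, use truncation throughout).
* Minimum-coancestry mating, tetraploidy, dominance and epistasis are not
  modeled.
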