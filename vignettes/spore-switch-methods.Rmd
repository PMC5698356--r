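---
title: "SporeSwitch: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SporeSwitch: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SporeSwitch)
```

SporeSwitch studies a life-history trade-off in filamentous fungi under
daily serial-transfer selection: within each growth cycle a colony must
divide its time between exponential hyphal growth and the production of
transferable propagules (single-celled conidia and suspended hyphal
fragments), because only propagules survive the small-aliquot transfer to
fresh medium. The package has three layers — a closed-form timing model, a
stochastic serial-dilution simulator built on it, and a GO-grouped ANOVA
pipeline for bulk expression tables — plus synthetic-data generators that
make every layer testable without external data.

## The propagule-production model

One cycle lasts `T` hours (default 24 h, the daily regime). Hyphae founded
by `P0` propagules grow exponentially at the specific rate `r_h` (per
hour) until the conidiation onset `t_c`, so the hyphal biomass at transfer
is

$$H_T = P_0\,e^{r_h t_c}.$$

After onset, conidia accumulate linearly at `r_c` conidia per hyphal unit
per hour,

$$C_T = r_c H_T (T - t_c),$$

and a fraction `f` of the hyphae fragments into transferable suspended
particles, giving the transferable total

$$P_T = f H_T + C_T.$$

Setting $dP_T/dt_c = 0$ gives the interior optimum

$$t_c^{*} = T + \frac{f}{r_c} - \frac{1}{r_h},$$

which `optimalOnset()` clamps to $[0, T]$. The clamp is exact, not a
heuristic: the sign of $dP_T/dt_c$ is the sign of
$f r_h + r_c\,(r_h (T - t_c) - 1)$, which is strictly decreasing in
$t_c$, so $P_T$ is unimodal on the interval — if the unclamped root lies
above $T$ the total is increasing everywhere and the boundary $T$ is the
argmax, and symmetrically for roots below zero. Three corners need stated
conventions, each covered by a test: `r_c = 0` with `f > 0` (fragments are
the only propagules; never switch, optimum `T`), `r_h = 0` (biomass cannot
grow; switching immediately maximizes production time, optimum 0), and
`r_c = f = 0` (no propagule route at all; an error, since $P_T \equiv 0$).

Two qualitative consequences are worth naming because the test suite
asserts them. Without fragmentation (`f = 0`) the optimum
$T - 1/r_h$ does not involve `r_c` at all: the production rate scales the
conidia count but not the best time to start. And under the equal-rates
case `r_h = r_c = r` the optimum $T + (f-1)/r$ increases in both `f` and
`r`, reaching `T` exactly at complete fragmentation — a fully
yeast-like, planktonic strategy with no conidia.

Counts in this layer are real-valued expectations; integerization is
deliberately deferred to the simulator's sampling step so that the model
layer stays deterministic. The model applies fragmentation to the *total*
hyphal biomass (Eq. for $C_T$ uses $H_T$, not $(1-f)H_T$); an alternative
in which fragmented biomass cannot conidiate would scale $C_T$ by
$(1-f)$ — we implement the stated form and note that the alternative only
rescales `r_c`, leaving the optimum structure unchanged.

Neither absolute rate magnitudes nor units beyond "per hour" are fixed by
the biology we model; the defaults `r_h = 0.3`/h (a doubling time near
2.3 h, fast-growing soil fungus territory) and `r_c = 1`/h respect the
ordering that conidia production rates exceed hyphal growth rates.

## The serial-dilution simulator

`runSerial()` iterates growth (`growCycle()`) and transfer
(`sampleTransfer()`). The transferred aliquot is `transferVolume` of
`cultureVolume` (default 0.1 mL of 10 mL, dilution `D = 100`). Sampling
is Poisson with mean `total/D` per genotype: propagules in a well-mixed
culture dilute independently, and population sizes are far above the
aliquot count, so the hypergeometric correction is negligible. A
deterministic mode (rounded expectations, round-half-even) exists for
fixed-point and decline-law checks.

The carrying capacity is a hard cap on *summed hyphal biomass* per
culture, applied by proportional rescaling across genotypes, because the
within-cycle resource dynamics are not modelled; the cap's only role is
to bound population size and make relative fitness frequency-independent.
Two closed forms anchor the tests: with per-capita transferable yield
$y < 1$ the expected census declines geometrically (slope $\ln y$ per
transfer, mean extinction transfer near $\ln N_0 / \ln(1/y)$), and with
$y > 1$ under a binding cap $K$ the transferred count plateaus at
$K\,(f + r_c (T - t_c))/D$.

Generation accounting: regrowth through a $1/D$ bottleneck takes
$\log_2 D$ doublings, i.e. about 6.64 generations per daily bout at
$D = 100$. Because rounded totals like "561" or "about 300" depend on
*when* rounding is applied, `totalGenerations()` takes the rounding rule
as an explicit parameter (`exact`, `one-decimal-floor` — 85 bouts of 6.6
give 561 — and `nearest-ten` — 45 and 85 bouts round to 300 and 560).

### The evolutionary mode

`runEvolution()` adds mutation at the bottleneck: each transferred
propagule founds a new genotype with probability `rate` (default 0.01).
Onset times step by a reflected Gaussian (sd 1 h) inside $[0, T]$;
fragmentation steps on the log-odds scale so it stays inside $(0,1)$.
Mutation is supplied per transferred propagule rather than per cell
division: it keeps the simulator at genotype granularity while the
within-cycle population is only an expectation. Selection is purely
emergent — genotypes differ in per-cycle yield, nothing else.

The parameter-recovery scenario (mutable `t_c`, fixed `f = 0.5`,
`r_h = r_c = 0.3`, `D = 100`, 300 transfers) uses a carrying capacity of
$10^6$ hyphal units, $10^4$ founding propagules and an initial onset of
16 h. These sizes were fixed once after a short pilot confirming the
regime is comfortably supercritical and mutation-limited rather than
drift-dominated; under them the population mean onset settles within a
fraction of an hour of the closed-form optimum (22.33 h), well inside the
mutation-kernel width.

## The expression pipeline

The pipeline consumes a locus x sample FPKM table (two genotypes,
`ancestor` and `derived`; three timepoints, 18, 22 and 24 h; replicated)
and a locus-to-GO-term map — both plain TSV. Upstream read alignment and
FPKM estimation are out of scope.

*Fold-change filter.* `foldChangeLoci()` keeps loci whose
replicate-mean FPKM differs between genotypes by more than
`thresholdLog2` (default 1, i.e. two-fold) at one or more timepoints. A
pseudocount (default 0.1 FPKM, configurable) guards zero denominators;
its value is a convention, not an estimate.

*Normalization.* `normalizeExpression()` averages replicates within each
genotype x time cell, applies `log(x + 1)` (natural log; base-2 logs are
reserved for fold changes) and divides by the per-locus sum over the six
cells. Every locus's shares sum to one, so downstream ANOVA reads
*relative* expression changes, with direction preserved. All-zero loci
get zero shares and a flag. Replicates are averaged *before*
normalization — the six-cell share is defined per locus, not per
replicate — so replicate variance propagates into the cell means rather
than entering the models as a factor.

*Global fit.* `globalFit()` collapses shares to a G x 2 x 3 cell-mean
table (mean over member loci; multi-term loci count in each of their
terms, mirroring how GO slim mappers assign membership, with no
down-weighting) and fits
`share ~ GO + genotype + time + GO:genotype + GO:time`. The residual
pools `genotype:time` and `GO:genotype:time`, so model df is $4G-1$ and
residual df $2G$ — 111 and 56 on the 28-term reference design. The F
statistic and adjusted $R^2$ are data-dependent summaries, not design
constants; only the df structure is asserted in tests. A constant
cell-mean table is reported as $F = 0$.

*Per-term tests.* `goGroupTests()` runs, per GO term, a locus-level
two-way ANOVA with the member loci as the error stratum. This is the one
place the package departs from the most naive construction, and the
reason is a constraint baked into the normalization: each locus's six
shares sum to one, so cells of the same locus are negatively correlated
and a pooled fixed-effects residual understates the variance of the
genotype contrast (by a factor of about 1.2 at six cells), inflating the
familywise error under the null. Testing each effect against its
locus-interaction stratum — the genotype main effect as a paired t-test
across the per-locus derived-minus-ancestor mean shares, the
genotype:time interaction as the repeated-measures F for a time effect on
those per-locus differences — respects the constraint exactly, and null
simulations then hold the Benjamini-Hochberg target. BH across terms at
`alpha = 0.05` is the default correction (any `p.adjust` method can be
substituted); terms with fewer than two loci are reported untested.
Directional calls carry the sign of the mean derived-minus-ancestor
share; temporal calls carry the sign of the per-time difference regressed
on time, so "increasing divergence" and "declining divergence" are
distinguishable.

*Deviation profiles.* `deviationProfile()` subtracts each term's grand
mean share from its genotype x time cell means; per term the six
deviations sum to zero by construction, which the tests assert at 1e-12.

## The synthetic-data generators

`makeGOUniverse()` builds a term universe (defaults: 28 terms, 25 loci
each, optional multi-membership). `simulateExpression()` then emulates
the reference design — 2 genotypes x 3 timepoints x 2 replicates, the
mapped loci plus 9300 unmapped background loci, about $10^4$ loci in all.
Baseline FPKM is log-normal (meanlog 2, sdlog 1.5), a conventional
right-skewed choice, not calibrated to any particular organism.

Planted effects are specified in the units the tested statistic uses:
share units. Writing $v_0 = \log(x_0+1)$ for a locus's baseline, a
planted derived-minus-ancestor share shift of $\delta$ is realized by
adding $6 v_0 \delta$ to the derived cells on the $v$ scale — a
first-order calibration under the six-cell share transform. Temporal
slopes add $s\,(t - \bar t)$ in the same units, replicate noise is
multiplicative log-normal on $x + 1$ with sd $6 v_0\,\sigma$ (about
$\sigma$ on the share scale, default 0.005), and fold-change loci have
their derived FPKM multiplied directly. The default planted truth mirrors
the structure such an experiment produces: 12 of 28 terms directional
(8 up, 4 down, 0.02 share units), 6 further terms temporal (4 increasing,
2 declining, 0.005 per hour).

What the generator does *not* emulate: count-level sampling noise and its
mean-variance relationship, correlated co-regulation within terms,
library-size artefacts, or annotation errors in the GO map. Passing the
recovery and error-control tests therefore demonstrates that the
statistics behave correctly under their own assumptions, not that those
assumptions hold for any particular real dataset.

`makeScenarioFixture()` provides three simulator fixtures — an
ancestor-like genotype (onset suppressed past the cycle end, no conidia
in 24 h), a derived-like genotype (early onset, conidia plateau orders of
magnitude higher within one cycle) and a near-extinction genotype whose
per-capita yield through the 1:100 bottleneck is below one, so it dies
out within about five daily transfers. All three are synthetic parameter
sets shaped to reproduce qualitative contrasts, not fits to measured
strains.

## Numerical choices and problem sizes

Tie-breaks in the brute-force grid argmax go to the earliest onset
(deterministic and reproducible). The brute-force/closed-form equivalence
is asserted at grid step $10^{-3}$ h over 1000 random draws; the
Euler-integration oracle for the census uses dt $= 10^{-3}$ h and agrees
within 0.1%. The evolutionary recovery check uses 20 seeds; the
extinction law 200 seeds; directional sensitivity 100 simulated universes
(effect = 3 noise sd, threshold 0.95); the null error-control simulation
300 universes against the BH target plus two binomial standard errors.
These sizes keep each property estimate's Monte-Carlo error well below
the tolerance it is compared against.

## Known limitations

The model treats one cycle in isolation: no lag phase (a configurable
germination lag is a natural extension; faster-germinating genotypes
would shorten the effective cycle), no within-cycle resource depletion
beyond the biomass cap, no spatial structure or attachment substrate, and
no epigenetic inheritance. The expression stage models exactly two
genotypes; multi-population designs need the tests run pairwise. FPKM
itself is taken as given — the pipeline boundary is the expression
table.
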