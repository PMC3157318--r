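---
title: "The cryptdrift model: crypt dynamics, niche succession and APC mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cryptdrift model: crypt dynamics, niche succession and APC mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptdrift)
```

## The model

`cryptdrift` simulates a colonic crypt as agents on an N x M lattice — the
crypt slit open and rolled out flat, so columns wrap laterally (a cylinder)
and row 0 is the stem-cell niche at the crypt base.  Each cell carries a
cycle state (quiescent, G1, S+G2, mitosis), a position, the time spent in
its current state, an age, a count of completed divisions, a *stemness*
value quantised in steps of `1/num_div_max`, the founding stem lineage it
descends from, and a two-allele APC genotype.

Every iteration (default 30 min) advances each cell by one rule: quiescent
cells with positive stemness enter G1; G1 and S+G2 accumulate time and
advance when their phase duration (TG1, and TC − TG1) is reached; a cell
entering mitosis divides within the same iteration.  Both division products
restart as quiescent cells, so the realised cycle is TC plus three steps
(one per phase transition and one quiescent step); with the default 24 h
stem cycle that is 25.5 h.  We state this convention explicitly because the
absolute iteration counts reported by the waiting-time experiments scale
with it.

Daughters are inserted into a neighbouring site with the priority: empty
north, empty east/west (random between two empties), empty south, then a
uniformly random occupied site among north/east/west.  Multi-occupancy is
allowed; migration then resolves it: wherever a site holds more than one
cell, the oldest non-stem resident moves up one row and pushes the whole
column of cells above it up by one.  Cells pushed past the top row are shed.
Stem cells are never displaced, and stem-cell daughters are inserted east or
west only, so the stem pool stays in the niche row.  Ties in age break
uniformly at random from the run's seeded stream, and divisions commit in a
seeded random order, which makes every run bit-reproducible from its seed
(`simulate_crypt(..., seed = )`).

## Symmetric division and the homeostat

A stem division is symmetric with probability `ps`; a symmetric division
either differentiates both daughters (probability `pd`) or keeps both as
stem cells.  The outcome probabilities are therefore

  P0 = ps * pd,   P1 = 1 - ps,   P2 = ps * (1 - pd).

`pd` is not a constant.  It is corrected each iteration by the stem-cell
census at the start of the iteration:

  pd = clip(Ns / N0 - 0.5, 0, 1),

which equals 0.5 at the target pool size, drops to 0 at half of it and
saturates at 1 at one-and-a-half times it.  A bias factor B multiplies the
*clipped* corrected probability (so the attainable range of the biased
probability is exactly `[0, B]` for B ≤ 1), modelling a mutant cell that
under-responds to the differentiation signal.  With B = 1 the stem pool
fluctuates around N0 in a roughly 8–13 band for N0 = 10; for B between 0.5
and 1 it settles at an elevated level; for B < 0.5, P2 exceeds P0 everywhere
and the pool grows without bound — runs then stop at the `max_stem_cells`
guard and are flagged, not averaged into succession statistics.

```{r homeostat}
ns <- 0:30
plot(ns, corrected_differentiation_probability(ns, 10), type = "s",
     xlab = "stem-cell census", ylab = "corrected pd")
```

Which census feeds the correction is a genuine modelling choice: the niche
"sees" crowding, and transit daughters do pass through the niche row.  We
implemented both readings.  With `ns_feedback = "niche_occupancy"` the
correction reads the total bottom-row occupancy; on the lattice this lets
terminally differentiated cells linger in niche columns, inflating the
census by 4–5 cells, dragging the true stem pool to about 6 and roughly
halving succession periods — inconsistent with the homeostatic behaviour
described above.  The default is therefore the literal reading,
`"stem_count"`: only stemness-1 cells count.

## Niche succession and the reduced model

Because lineages go extinct when both daughters differentiate and expand
when both stay stem, the niche drifts to monoclonality: the first iteration
at which a single founding ancestor owns every stem cell is the succession
time.  With `ps = 0` no lineage can die and the period diverges; it falls
as `ps` grows and rises as B falls.

The division-type draw depends on the lattice only through the stem census,
so the stem compartment can be simulated alone.  `stem_only_sim()` is a
deliberately independent event-driven implementation (pure R, per-lineage
division clocks, no lattice) used as an oracle: on matched parameters its
succession-period distribution is statistically indistinguishable from the
full model's (Welch test at alpha = 0.01 in the test suite), and for tiny
systems (two founders, all divisions symmetric) it is checked against exact
enumeration of the absorbing chain.  The test suite leans on it for the
slowest succession points, where the lattice model would dominate the run
time without informing the comparison.

## The APC layer

Each cell carries two binary APC alleles.  `"FAP"` initialisation makes
every founding stem cell heterozygous (germline first hit); `"SPORADIC"`
marks exactly one seed-chosen founder.  At every division each product
draws once: a heterozygous product's remaining wild-type allele flips with
probability `mutation_prob`.  Flips are permanent and inherited; wild-type
first hits are not modelled, since the simulated experiments all start from
an existing heterozygote.  The per-product (rather than per-division)
sampling unit is our reading of an ambiguous rule and is stated here for
reproducibility; at the small rates used it changes waiting times only
through a factor close to the mean number of eligible products per
division.

A heterozygous phenotype can override `ps`, the bias B, or rescale the
cycle time (`het_cycle_mult = 0.5` doubles the division rate).  The
second-hit endpoint counts stem cells only by default
(`second_hit_scope = "STEM_ONLY"`): transit cells wash out of the crypt
within days, so only stem-cell hits can matter for initiation.  The
any-cell endpoint is available for sensitivity analysis and is never later
than the stem-only one.

## Experiments, replicate counts and numerical choices

The experiment helpers derive per-replicate seeds from a master seed by a
fixed counter scheme (`replicate_seeds()`), so every table is reproducible.
Defaults: 100 replicates for fixation fractions (binomial SE ~4–5 points),
20–30 for period and waiting-time means; the acceptance script uses 100 and
30.  Runs that end without the event of interest (overflow, iteration cap)
are censored: excluded from means, counted and reported.

Monte-Carlo estimates from this model have large spread — succession and
second-hit times have coefficient of variation near 0.65 and 1.0 — so the
acceptance tests compare reference values at plus/minus three standard
errors of the estimator at the stated replicate counts, a fixed rule chosen
once.  Degenerate inputs are handled explicitly: a single founding lineage
is monoclonal at iteration 0; zero stem cells is an extinction flag, not a
succession; `max_iterations = 0` returns the initial state, which is how
the tests inspect initial conditions.

Known limitations: the lattice has no cell mechanics or adhesion, no Wnt
signalling, no crypt fission (growth beyond the guard is flagged instead),
and no post-second-hit phenotype — a run ends when the second hit appears.
The generator emulates a ~500-cell crypt section with a 10-cell niche;
absolute periods and waiting times are meaningful for trends across
parameters, not as per-crypt physiological constants.

```{r example, fig.width = 6, fig.height = 4}
run <- simulate_crypt(crypt_params(ps = 0.2), seed = 1)
run
plot(run)
```
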