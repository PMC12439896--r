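---
title: "An episodic-like memory model: what, when, where"
author: "cuttlemem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An episodic-like memory model: what, when, where}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuttlemem)
```

## The model

Episodic-like memory is the behavioral recall of *what* happened, *when*
it happened and *where* -- demonstrated in scrub jays, cuttlefish and
other species that cannot give a declarative report.  `cuttlemem`
implements a deliberately parsimonious model of this capacity: a dense
3-D tensor of expected reward values,

$$\mathrm{epimem}[\mathrm{what},\, \mathrm{when},\, \mathrm{where}]$$

indexed by object identity, hour of the day, and grid cell.  The tensor
is a content-addressable store: binding any subset of the three indices
returns the matching expected values ("the values of shrimp at hour 3
over all locations"), and the unbound entries can be reduced by max, sum
or mean depending on what the behavior needs.  Learning is the delta
rule (Rescorla-Wagner):

$$\Delta v = \alpha\,(r - v),$$

applied to exactly one entry whenever the agent eats a prey (reward $r$),
fails to find a remembered prey ($r = 0$, an *extinction* update), or is
caught by a predator ($r$ negative).  Action selection passes a vector of
values through the softmax (Boltzmann) rule
$p_i = e^{\beta v_i} / \sum_j e^{\beta v_j}$ with inverse temperature
$\beta$.  A published variant of this rule places $\beta$ as a
multiplicative factor outside the exponential, where it cancels between
numerator and denominator; we use the standard Boltzmann form, which
coincides with the multiplicative form at $\beta = 1$ -- the value both
scenarios use -- so simulated behavior is unaffected.

Three design properties matter for everything downstream:

* a fresh memory is exactly zero everywhere -- the agent begins with no
  expectations, and exploration is driven by the fixed value of the
  `roam` action (0.5), not by optimistic initialization;
* only `deltaUpdate()` changes entries; queries are pure reads;
* updates land at the prey's *actual* cell (or the predator's cell), so
  spatial knowledge accumulates only where events really occurred.

```{r}
mem <- episodicMemory(c("crab", "shrimp"), nWhen = 3, width = 8, height = 8)
mem <- deltaUpdate(mem, "shrimp", when = 3, where = cellIndex(7, 7, 8), r = 4)
queryMemory(mem, "shrimp", when = 3, reduction = "max")
```

### Index conventions

Internally R is 1-based, and `queryMemory()`/`deltaUpdate()` take 1-based
`when` and `where` indices.  The simulated day, however, is narrated
0-based (hour 0 is the first hour), and all record tables, memory dumps
and `mttTable()` output use 0-based hours and 0-based `(x, y)` cell
coordinates with the origin at the top-left.  The delay labels used in
choice analyses are `hour + 1` hours, matching the behavioral convention
in which the final hour of a 3-hour day is the "3-hour delay".

## The gridworlds

Both scenarios share one movement vocabulary: creatures make king moves
(8 directions), so distance is the Chebyshev metric
$\max(|\Delta x|, |\Delta y|)$, which makes "steps" and "distance"
identical units.  "Vision < 2" therefore means eating requires distance
$\le 1$; "vision < 4" means the predator pursues at distance $\le 3$.
Moves are clipped at walls (and at region edges when an agent searches
within one region).  Deterministic travel toward a remembered location is
a sign-step per axis, reaching the target in exactly the Chebyshev
distance -- the model assumes the agent knows how to get where its memory
points, an *a priori* ability kept outside the memory itself.

### Delayed-reward scenario

An 8x8 grid, 3-hour days of 100 steps, 100 days, 100 runs.  Crab (reward
1.0) sits at (7, 0) every hour; shrimp (reward 4.0) sits at (7, 7) --
every hour during the first 50 days (phase 1), only the final hour
afterwards (phase 2).  The agent starts each hour at (0, 4), picks one of
hunt crab / hunt shrimp / roam by softmax over the per-object *maximum*
values at the current hour plus the fixed roam value, and then either
walks to the remembered best cell or random-walks.  Parameters:
$\alpha = 0.10$, $\beta = 1.0$, roam value 0.5.

Two mechanisms had to be made explicit where the behavioral description
leaves them open:

* **Extinction.**  If updates occurred only when prey is present, values
  learned in phase 1 would freeze and the agent could never discover the
  new contingency.  When a hunt arrives at the remembered cell and the
  target cannot be eaten there, we apply a single delta update with
  $r = 0$.  This is the minimal mechanism that lets the 1-hour and 2-hour
  shrimp expectations decay in phase 2 while the 3-hour expectation
  survives.
* **Ties.**  `which.max` breaks value ties at the lowest flat cell index,
  so a fresh memory sends early hunts to a fixed (empty) corner.  Early
  competence comes from roaming encounters, reproducibly under the run
  seed; we prefer deterministic tie-breaks over tie randomization because
  exploration pressure is already supplied by softmax plus the roam
  action.

After eating, the agent takes no further action until the next hour, and
it can eat at most one prey per hour.

### Predator-prey scenario

A 12x12 grid tiled by nine 4x4 regions (row-major 0-8), 6-hour days of
100 steps, 200 days.  Crab (reward 1.0) is placed uniformly in region 8
every hour; shrimp (reward 4.0) uniformly in region 6 during hours 2-5; a
predator appears during hours 1-3, placed uniformly on the left side
(x < 6).  The agent starts each hour at (6, 0).  Each step the agent
moves first, then the predator (a fixed order chosen for
reproducibility); the predator pursues when it can see the agent and
roams otherwise, and an uncamouflaged agent at distance $\le 1$ after the
predator's move is caught, ending its hour.

The penalty parameter (8) enters the delta rule as $r = -8$, so predator
entries are non-positive.  That one sign choice does double duty: in the
*where* read-out, predator memories discount dangerous regions; in the
*what* read-out, the hide action's value is the negated predator sum, so
learned danger directly drives hiding.  Predator memories are written
only when the agent is actually caught (at the predator's cell); mere
sightings do not update, keeping the stored quantity an experienced
penalty rather than a surveillance map.

Two query modes turn the same memory into behavior:

* **what_when** -- per-object sums over all locations at the current hour
  give values for hunt crab / hunt shrimp / hide / roam.  A hunt heads to
  the center of the region where the chosen object's remembered value is
  largest, then searches that region randomly.
* **when_where** -- per-region sums over all objects give values for the
  nine go-to-region actions plus roam; the agent searches the chosen
  region and opportunistically eats whatever it finds.  This mode has no
  hide action, which is why it stays exposed during predator hours.

A 4x4 block has no exact center cell; we fix the cell at
$(x_0 + 1, y_0 + 1)$ (the upper-left of the four central candidates) for
reproducibility.  Hunts into a region where the target is absent apply
one extinction update at that center cell on arrival; the when_where mode
applies no extinction because its actions have no designated target.

## What the simulation does and does not emulate

The generator *is* the study design: schedules, rewards, grid sizes and
run counts above are the experimental conditions, not free dials.  It
reproduces the structure of the behavioral experiments -- fixed
contingencies, stationary prey, a single Markovian predator -- and
nothing more.  Real foraging data would add prey movement, satiety,
multi-predator scenes, continuous space and time, and sensory noise, none
of which are modeled.  Passing behavioral checks here shows that the
memory architecture *can* support delayed-reward recall and risk-shaped
foraging under these controlled conditions; it does not show the model
fits field data.

## Numerical choices

* Softmax is computed with a max-shift, so region sums of tens of value
  points cannot overflow; the output sums to 1 within $10^{-12}$.
* Region sums and maxima are exact floating-point sums over at most 144
  entries; no accumulation tricks are needed at this scale.
* One RNG stream per run, seeded as `base_seed + run - 1`
  (`deriveSeeds()`); per-hour direction draws are generated in blocks,
  agent first, then predator.  Given a config and base seed, every record
  CSV is byte-identical across repeats.
* Memory dumps print values with 17 significant digits, making the
  CSV round trip bit-exact.
* Degenerate inputs are rejected early: out-of-range indices name the
  offending dimension, empty cell sets are a domain error, probability
  vectors must be non-negative and sum to 1 within $10^{-6}$.

## Problem sizes used in the test suite

Unit and property tests run on toy worlds (a few days, 20-40 steps per
hour) because every mechanism they check is size-independent.  The
behavioral checks use the study sizes themselves: 100 runs x 100 days for
the delayed-reward scenario and 20 runs x 200 days per query mode for the
predator-prey scenario -- large enough that medians across runs are
stable, small enough to run comfortably on one CPU.

## Known limitations

* The tensor is dense and does not scale: memory grows as
  $W \times T \times L$, and no sparse coding or hashed query keys are
  provided.
* The only learning rule is the delta rule; there is no eligibility
  trace, no forgetting outside explicit extinction visits, and no
  generalization across neighboring cells or hours.
* Path planning is assumed, not learned.
* Time is a clean hour index; the model is silent on how a biological
  clock would furnish it.
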