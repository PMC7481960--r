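---
title: "Stochastic platelet supply-chain optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic platelet supply-chain optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The decision problem

A regional blood center distributes platelets to `K` hospitals. Platelets
leave the center with at most three days of usable shelf life; a unit whose
remaining life reaches zero at a day's end is discarded. Hospitals face
random daily transfusion demand, the center faces random daily donor supply,
and both sides review their inventory daily (configurable review periods).
A hospital order placed on day `t` is shipped the same day and arrives
`LT` days later, so a unit shipped at age `l` arrives with `l − LT` usable
days — shipping anything with `l ≤ LT` would deliver an expired unit, which
the model forbids outright. Hospital lead times are therefore restricted to
0–2 days. The blood center's own procurement is supply-driven: it processes
whatever the donor population provides, with a lead time (collection plus
testing) of `LTBC` days.

Unmet hospital demand is not lost: it is covered the same day by an
emergency shipment, at a much higher per-unit price than a regular order.
The center serves emergency demand from whatever stock remains after the
regular orders; what it cannot serve, it procures from other centers. The
planner's problem is to choose the regular order quantities — before demand
and supply are known — so that the expected total cost of purchasing,
holding, shortage (emergency procurement) and outdating is minimal.

# Two-stage scenario formulation

Uncertainty is handled by sampling `S` joint demand/supply scenarios over
the `T`-day horizon and weighting them uniformly. The first stage (identical
in every scenario — the nonanticipativity requirement) consists of the
center's committed shipments by age, `BCTHP[k,t,l]`; hospital orders are
their age sums and hospital receipts are their lead-time-lagged images.
Rather than carrying per-scenario copies of the first-stage variables plus
equality constraints, the implementation creates them once and shares them
across scenarios — an equivalent but materially smaller formulation. The
second stage carries, per scenario, the FIFO fulfillment cascades at the
hospitals, the split of committed age-3 shipments between on-hand fresh
stock and external procurement, and the center's emergency cascade.

Two further substitutions shrink the model without changing its decisions:
opening inventories are replaced by the previous day's one-age-older
leftovers (the overnight-aging identity), and the center's order stream is
fixed to the realized supply (accumulated onto review days when the review
period exceeds one day, and lagged by `LTBC`). The horizon starts cold: no
pre-horizon orders are in the pipeline, and the configured initial
inventories are the only day-one stock.

Fixed shipping costs attach to binary shipment indicators through big-M
constraints, with `M = max(30, 3⌈μ_tot + 6σ_tot⌉)` aggregated over hospital
demand — provably above any useful shipment, small enough not to hurt the
relaxation badly. The inbound-shipment indicator at the center is fixed by
the realized supply and folded into the objective constant.

# FIFO semantics and complementarity

FIFO issuing is written, as is standard, as paired balances
`RD_l − LY_l = (remaining demand after age l−1) − (available stock of age l)`
with both `RD` (remaining demand) and `LY` (leftover) nonnegative. The
intended semantics is definitional: `RD_l` and `LY_l` are the positive and
negative parts, i.e. `RD_l · LY_l = 0`. A linear program only honors that
when it is cheapest to do so, and with realistic cost vectors it is *not*
always cheapest, in two distinct ways:

* **Free disposal.** Inflating an `(RD_l, LY_l)` pair while deflating
  `LY_{l+1}` expires surplus stock a day early. When stock is bound to
  expire unused anyway, this saves one night of holding cost — strictly
  profitable whenever the holding rate is positive. A physical FIFO
  warehouse cannot do this.
* **Phantom stock / withholding.** In the center's emergency cascade, if the
  terminal unmet-emergency quantity carries no cost, paired inflation can
  manufacture stock out of nothing, and serving emergency demand can be
  refused to keep stock for future sales. Pricing the terminal shortage
  closes the profitable versions of both, but cost-neutral *age swaps* of
  the leftovers remain possible and corrupt the inventory-age bookkeeping.

The package therefore enforces complementarity structurally, with big-M
disjunctions (`RD ≤ Mz`, `LY ≤ M(1−z)`), but never monolithically — that
many binaries interact badly with the inventory dynamics and make
branch-and-bound intractable at realistic sizes. Instead `solve_model()`
uses a two-phase scheme:

1. solve the disposal-relaxed mixed-integer program (fast; also yields a
   dual bound on the true optimum);
2. if the incumbent violates complementarity anywhere, fix the first stage —
   the scenarios then decouple — and re-solve only the violating scenarios
   as small single-scenario programs with every disjunction active;
3. stitch the scenarios back together, recompute the objective from the
   unperturbed cost vector, and report the optimality gap certified against
   the phase-1 dual bound.

The stitched solution is feasible for the fully FIFO-constrained program,
and because the relaxation's only advantage is the small disposal profit,
the certified gap is typically a fraction of a percent (about 0.5% on the
reference network). `build_model(strict_fifo = TRUE)` still offers the
monolithic formulation for small instances and degenerate cost vectors
(e.g. zero holding cost), where the lazy argument would not apply.

Two numerical details belong here. End-of-horizon leftovers at the center
are uncosted, which leaves the final day's emergency bookkeeping degenerate;
a 0.01-cent tie-break is added to those two variables for the solver only,
and the reported objective is always recomputed from the true costs.
Integrality is declared for all flow variables; `relax = TRUE` drops it for
fast property checks and is labelled as such in the result.

# Blood-center shortage pricing

The cost list prices the center's shortage as its total external
procurement: regular backing (`SHRBC`) plus unmet emergency (`SHEBC`). That
is the default (`bc_shortage_pricing = "total"`). It has a consequence worth
understanding: a hospital shortage unit then costs the system the hospital's
emergency price *and*, when the center's leftovers are exhausted (the usual
case), the center's external-procurement price on top — so the optimizer
orders up rather aggressively to avoid shortages.

An alternative accounting (`"regular"`) prices only the regular-stage
external procurement, on the argument that the hospital's emergency price is
itself the pass-through procurement price for those units (numerically it
approximately equals the purchase price plus the center's external rate), so
pricing `SHEBC` again double-counts the same physical units. Under this
accounting the unpriced cascade end must be closed structurally (the
phantom-stock problem above), which makes the relaxation phase itself a hard
MIP; the option is provided but is far slower and is not the default.

# Scenario generation

Each entity draws from its own child RNG stream, derived from the master
seed by a fixed integer map (hospital `k` → lane `k`, center → a reserved
lane), so adding a hospital never reshuffles another entity's draws and a
seed fully determines the experiment. Draws are `round(max(0, N(μ, σ)))` —
demand and supply are whole units and cannot be negative; with the reference
coefficients of variation (0.16 or less) the truncation bias is negligible.
The generator emulates independent, stationary daily demand. Real platelet
demand has weekday structure, serial correlation and occasional surges, and
real supply responds to donation campaigns; none of that is modelled, so
passing tests here says nothing about calendar effects. Scenario
probabilities are uniform `1/S`.

The sensitivity knob `apply_cv_setting(cfg, cv)` rescales every
distribution's standard deviation to `round(cv · mean)`, recomputed from the
mean so the operation is idempotent.

Initial inventories are inputs with a deliberate default — one mean day of
demand (or supply, at the center) as age-2 stock — because carried stock of
exactly one review cycle is the natural steady-state order of magnitude.
They are configuration values, not estimates.

# KPI definitions

`kpi_summary()` reports, per entity, average daily units of shortage,
outdating, holding (opening stock) and purchases, averaged over days and
probability-weighted scenarios; and overall the expected cost per day per
scenario together with the best and worst scenario's daily cost and the
probability-weighted *population* standard deviation across scenarios
(configurable in principle; population normalization is the natural choice
for a complete sampled ensemble). Cost parameters are given in cents;
all cost summaries are reported in dollars. The center's "purchased" row is
its expected processed supply. The center's shortage row is the total
(regular external plus unmet emergency), regardless of which of the two
pricing conventions the objective uses.

# Sensitivity experiments

`run_cv_sweep()` visits a grid of coefficients of variation;
`run_cost_settings()` visits the 17-setting cost grid (`CSET1` the base,
`CSET2–9` halving and `CSET10–17` multiplying by 1.5 exactly one cost family
each). Within a replication every setting shares the same master seed —
common random numbers — so differences between settings are attributable to
the parameters, not to sampling. Expected optimal cost is non-decreasing in
any single cost coefficient (a pointwise-larger objective cannot have a
smaller minimum), and empirically the expected cost increases monotonically
in the coefficient of variation; both are exercised in the test suite at
reduced scale.

Desk-scale defaults are `T = 60` days and `S = 20` scenarios with three
seeds — small enough that a full sweep fits interactive use on one CPU,
large enough that warm-up effects do not dominate. A caveat that matters
when comparing against full-scale runs (`T = 300, S = 100`): the cold start
means the center receives nothing for the first `LTBC` days, and that
warm-up share weighs five times more at `T = 60` than at `T = 300`, raising
the per-day average cost by roughly ten percent on the reference network.

# Rolling horizon

`rolling_horizon()` repeatedly solves a window, implements only its first
days against a held-out realization, advances the age-stratified inventories
through the event simulator, and re-solves with fresh scenario draws (a
forecast update). The realized cost of the concatenated policy is evaluated
by the replay oracle and is bounded below by the clairvoyant optimum on the
same realization. Shipments still in transit at a window boundary are not
credited to the next window's optimization (they are, of course, part of the
realized replay); with implementation spans at least as long as the lead
times this conservatism is minor.

# Known limitations

* Single blood product, single blood type, no inter-hospital transshipment.
* Demand/supply are independent normals; no calendar or correlation
  structure.
* The certified optimality gap of the two-phase scheme is conservative: it
  is measured against the disposal-relaxed bound, so the reported gap
  overstates the true distance to the FIFO-constrained optimum.
* The "regular" shortage accounting is exact but slow at scale.
* Emergency units are modelled as consumed the day they are delivered; they
  never enter hospital inventory.
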