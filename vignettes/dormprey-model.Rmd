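---
title: "The dormancy predator-prey model: equations, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dormancy predator-prey model: equations, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormprey)
```

## The model

`dormprey` simulates the competition between two prey species under a common
predator. The *perennially active* (PA) prey $p$ has the better traits: a
higher maximum growth rate and no overhead. The *dormitive* prey exists in
two interconvertible forms — an active, reproducing form $y_1$ and a sterile
dormant form $y_2$ that predators take far less efficiently. On its own,
each dormitive form is a losing strategy: the active form grows more slowly
than $p$ and wastes reproductive effort on dormant offspring; the dormant
form cannot reproduce at all. The interesting regime is where alternating
between the two losing forms beats the superior competitor — a
population-dynamic analogue of Parrondo's paradox.

The densities (mg L$^{-1}$) evolve as

$$
\begin{aligned}
\dot p   &= r_p\Big(1-\tfrac{p+y_1}{K}\Big)p - f_p(p)\,z,\\
\dot y_1 &= r_y\Big(1-\tfrac{p+y_1}{K}\Big)\mu(z)\,y_1 + \alpha y_2 - f_{y_1}(y_1)\,z,\\
\dot y_2 &= r_y\Big(1-\tfrac{p+y_1}{K}\Big)\big(1-\mu(z)\big)\,y_1 - \alpha y_2 - f_{y_2}(y_2)\,z,\\
\dot z   &= \big(k_p f_p(p) + k_{y_1} f_{y_1}(y_1) + k_{y_2} f_{y_2}(y_2)\big)z - d_z z,
\end{aligned}
$$

with Holling type-II predation $f_q(q) = c_q q / (1 + c_q h_q q)$ and the
sigmoid dormancy-allocation function

$$
\mu(z) = \chi + \varphi\,\big[1+\exp\big((z-\eta)/\sigma\big)\big]^{-1},
\qquad 0 \le \chi \le \chi + \varphi \le 1 .
$$

Three structural assumptions are built in: the dormant form is sterile; it
does not contribute to the crowding term (only $p + y_1$ compete for the
carrying capacity $K$); and predator mortality is density-independent. With
$y_1 = y_2 = 0$ the system is exactly the Rosenzweig–MacArthur two-species
model, which is why enrichment (raising $K$) destabilises the cycles — the
classical paradox of enrichment — and why the evasive dormancy strategy
pays off precisely in rich environments.

`dormprey_params()` carries the reference parameterisation
($r_p = 0.55$, $r_y = 0.5$, $K = 11$, $d_z = 0.2$, $\alpha = 0.05$,
$k_p = k_{y_1} = 0.5$, $k_{y_2} = 0.25$, $c_p = c_{y_1} = 1$,
$c_{y_2} = 0.4$, $h_\ast = 0.5$, $\eta = 1$, $\sigma = 0.1$, $\chi = 0.2$,
$\varphi = 0.75$) and the reference initial state $(2, 2, 0, 1)$. Two unit
notes, recorded here rather than silently changed anywhere else: growth
rates are treated as day$^{-1}$ (consistent with $d_z$ and the dynamics),
and $\chi$, $\varphi$ as dimensionless (required for $\mu \in [0,1]$),
even though published parameter tables for this model list both with
concentration units.

## Integration

Trajectories are produced by deSolve's adaptive explicit Runge–Kutta (2,3)
pair of Bogacki and Shampine (`method = "ode23"`) at
`rtol = atol = 1e-8`. The right-hand side is implemented twice: in C (the
default, because parameter sweeps run hundreds of 3000-day integrations)
and in R (`derivatives()`, the documented reference); a test holds the two
trajectories together. Numerical choices worth knowing:

* **Dense output.** Samples every `output_dt = 0.1` day, which resolves the
  25–50-day cycles to well under 1% of a period. The sampling grid is
  presentation only; halving it moves the reversal time by less than a
  tenth of a sample.
* **Negative undershoot.** Densities decay to extreme ranges
  (below $10^{-100}$) without event handling; compartments are never
  zeroed. The right-hand side clamps densities at zero only inside the
  functional responses and the crowding term, so a sub-tolerance negative
  excursion cannot destabilise the integration, while stored trajectories
  keep the raw solver output (a stored value below $-10^{-6}$ aborts with
  an error).
* **Sigmoid overflow.** The exponent $(z-\eta)/\sigma$ is clamped at
  $\pm 700$; beyond that $\mu$ returns the exact asymptote instead of NaN.
* **Reduction oracle.** `rm_reference()` integrates an independently coded
  two-species Rosenzweig–MacArthur system, *embedded* in the
  four-dimensional phase space with the dormitive compartments pinned at
  zero. The embedding matters: the step controller's error norm is an RMS
  over state components, so a bare two-dimensional integration takes
  slightly different steps and drifts by $\sim 10^{-3}$ over 500 days for
  step-control reasons alone. Embedded, the reduction identity holds to
  machine precision.
* **Accuracy cross-check.** Against a (4,5) pair at `1e-10`, states agree
  to better than $10^{-3}$ through the transient ($t \le 100$). Over
  longer horizons the comparison is made on metrics (reversal time within
  half a day, identical winners), because state-space discrepancy along a
  steep limit cycle is dominated by tolerance-proportional phase drift and
  grows to $\sim 10^{-1}$ by $t = 500$ for *any* pair of tolerant
  integrators — it says nothing about the quantities the model reports.

## Metrics

* **Cycle peaks** (`find_peaks()`): interior strict local maxima with a
  plateau-midpoint rule; quadratic refinement through the three samples
  around each maximum resolves peak times below the sampling interval; a
  prominence floor of $10^{-6}$ mg L$^{-1}$ ignores solver-scale ripple on
  near-extinct series.
* **Reversal time** $T_w$ (`reversal_time()`): the time of the first $y_1$
  peak strictly exceeding the *most recent preceding* $p$ peak ($y_1$
  peaks before $p$'s first peak are skipped; after $p$'s collapse its last
  recorded peak is the standing benchmark). This pairing reproduces the
  reference values ($T_w = 195.0$ at $K = 13$, $89.2$ at $K = 20$)
  directly, so no alternative pairing was needed.
* **Extinction time** (`extinction_time()`): first sample time from which
  a species stays below the threshold (default $10^{-3}$ mg L$^{-1}$,
  three orders below the initial densities; the model itself defines no
  numeric extinction) through the end of the run. Times are reported raw;
  headline values are also quoted to the nearest 10 days, the granularity
  at which such events are usually read off figures. One caveat this
  definition makes visible: at the reference parameters the PA prey's last
  macroscopic cycle collapses just after $t = 370$, but a residual ripple
  (peak $0.068$ mg L$^{-1}$ near $t = 416$, confirmed across integrators
  and tolerances) keeps the density above $10^{-3}$ until $t \approx 420$.
  A microscopic threshold therefore dates this extinction at 420, while
  any threshold above the ripple ($\gtrsim 0.07$) dates it at 370 — there
  is no threshold under which the event reads as an intermediate value,
  and figure-level readings of the collapse fall in between.
* **Winner classification** (`classify_winner()`): compares the maxima of
  $p$ and $y_1$ over a late *stable window* (default days 2800–3000). The
  larger maximum wins if it clears the extinction threshold; exact ties
  and doubly-extinct windows are `"none"` (no tie category exists in the
  winner maps, and ties below resolution should not invent one).

## Parameter sweeps

`run_grid()` scans any two parameters (axes may tie several fields, e.g.
$k_p = k_{y_1}$) over a grid; each feasible cell is an independent
integration from $(2,2,0,1)$ classified over the stable window; cells that
violate joint constraints — $\chi + \varphi \le 1$, or the panel-F
assumption $c_{y_2} \le \min(c_p, c_{y_1})$ (the dormant form must not be
*easier* to catch) — are masked infeasible, preserving the grid shape.
`figure3_panels()` packages the six canonical scans. Axis ranges are not
fixed by the published analysis, so the defaults bracket the reference
values and the regime shifts the model exhibits: $K \in [5,25]$,
$\alpha \in [0,1]$, $d_z \in [0.05,0.5]$, $\chi, \varphi \in [0,1]$,
$\eta \in [0.2,3]$, $\sigma \in [0.01,1]$, $k \in [0.1,0.9]$,
$c \in [0.2,2]$, at a default resolution of $21 \times 21$
(configurable; the test suite uses $11 \times 11$, about 130 integrations
per panel, which resolves every qualitative feature of the winner maps).

One boundary is worth stating precisely: with full-range switching tied as
$\varphi = 1 - \chi$, the dormitive prey wins decisively up to
$\chi = 0.7$ on a step-0.1 grid (the PA prey goes extinct by $t = 365$
there) and loses from $\chi = 0.75$; the winning region's edge lies in
$(0.70, 0.75)$. Coarser grids put the last winning grid point at 0.6.

## Scope and limitations

The model is deterministic and non-spatial; there is no demographic noise,
no evolutionary dynamics of the switching function, and one dormitive
morph pair. Solver work is the only computational cost: a 3000-day
integration takes well under a second with the compiled right-hand side.
The scenario presets (`scenario_presets()`) are parameter bundles, not
data; nothing in the package is fitted to observations, so agreement with
any real predator–prey system (zooplankton resting eggs, microbial
sporulation, phage lysogeny are the usual motivating examples) is
qualitative at best: the parameterisation descends from zooplankton
modelling literature, and real systems add seasonality, stochasticity and
spatial refuges that this model deliberately omits.
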