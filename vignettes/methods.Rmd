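---
title: "Methods: automated parameterisation of dynamic metabolic models"
author: "dynamet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated parameterisation of dynamic metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynamet)
```

## The problem

Constraint-based (stoichiometric) models of metabolism are available at
genome scale, but turning one into a *dynamic* model — a system of ODEs
whose simulation shows how metabolite concentrations respond to a
perturbation — requires a kinetic parameter for every Michaelis constant,
catalytic rate, equilibrium constant, enzyme level and initial
concentration. Almost none of these have been measured for most
organisms, measurements that do exist are scattered over databases with
incompatible identifier schemes, and a parameter set assembled naively
will violate thermodynamics (e.g. a cycle of reactions whose equilibrium
constants multiply to something other than one, creating a perpetual
motion machine).

`dynamet` automates the whole chain: it parses a reaction network from
SBML, searches registered databases for measured kinetic quantities by
exhaustive identifier-path translation, combines the measurements with
broad pseudo-priors in a thermodynamically constrained Bayesian update
("parameter balancing"), translates the network into common modular rate
law ODEs, simulates them, optionally reduces the network by flux
variability analysis, and quantifies — on synthetic gold-standard systems
— how much parameter knowledge is needed before the simulated dynamics
are trustworthy.

## Quantities and constraints

All kinetic quantities are expressed as linear functions of a *basic*
vector: standard chemical potentials $\mu^\circ_i$ (kJ/mol, linear
scale), and natural logs of the Michaelis constants $k^M_{ji}$ (mM), the
geometric-mean catalytic rates $k^V_j$ (1/s), the enzyme concentrations
$u_j$ (mM) and the metabolite concentrations $c_i$ (mM). The dependent
quantities follow through fixed linear maps, with $n_{ij}$ the signed
stoichiometric coefficient, $h_j$ the (fixed) cooperativity and $RT$ in
kJ/mol:

$$\ln k^{eq}_j = -\frac{1}{RT}\sum_i n_{ij}\,\mu^\circ_i, \qquad
\ln k^{cat\pm}_j = \ln k^V_j \mp \frac{h_j}{2}\sum_i n_{ij}
\left(\mu^\circ_i/RT + \ln k^M_{ji}\right),$$

$$\ln v^{max\pm}_j = \ln u_j + \ln k^{cat\pm}_j, \qquad
\mu_i = \mu^\circ_i + RT\ln c_i, \qquad
R^A_j = -\sum_i n_{ij}\,\mu_i.$$

Two classical constraints are then *structural*, not numerical: the
Haldane relationship
$h_j \ln k^{eq}_j = \ln k^{cat+}_j - \ln k^{cat-}_j + h_j\sum_i n_{ij}
\ln k^M_{ji}$ holds identically for any basic vector, and the Wegscheider
conditions ($\sum_j \gamma_j \ln k^{eq}_j = 0$ for every stoichiometric
null vector $\gamma$) hold because every $\ln k^{eq}$ descends from the
same potentials. Anything derived through the dependency rows — balanced
medians and posterior draws alike — is thermodynamically consistent *by
construction*; the residual checks in the package assert this to $10^{-9}$
but cannot fail unless the rows themselves are wrong.

A note on the Wegscheider check: the null space is taken over the
stoichiometric matrix of *all* metabolites that carry a chemical
potential. Restricting the rows to non-boundary species would admit null
vectors whose cycle sums involve potentials of the excluded species and
are not zero for any consistent parameter set; under the all-metabolite
convention, "cycles" include through-pathways across exchange reactions,
and their log-sums vanish too.

## The Bayesian update

Each basic quantity carries a broad pseudo-prior (defaults: $k^M$ median
0.1 mM, $k^V$ 10/s, $u$ 0.01 mM, $c$ 0.1 mM, all with log-std $\ln 10$;
$\mu^\circ$ mean 0, SD 500 kJ/mol — deliberately weak). Each measurement
or database record becomes one Gaussian observation row: an identity row
for a basic quantity, a dependency row for keq/kcat/vmax records, values
log-transformed, noise variance the squared record log-std (default
$\ln 2$, i.e. a multiplicative spread factor of two, when a source
reports no uncertainty). The posterior is the standard conjugate update,
computed by Cholesky factorisation with a $10^{-10}$-scaled jitter retry;
with no measurements the posterior *is* the prior, exactly.

Because an unmeasured $\mu^\circ$ is essentially unconstrained under the
weak prior, the package follows the parameter-balancing practice of
placing pseudo-priors on *dependent* quantities too: soft rows for
$k^{eq}$ (median 1) and $k^{cat\pm}$ (median 10/s), log-std $\ln 10$,
generated by `pseudoMeasurementRecords()` and applied by default in
`balanceNetwork()`. These keep chemical-potential *differences* in a
physically plausible range (absolute levels remain unidentified, and
cancel in every derived quantity) while remaining weak enough that even a
handful of real measurements dominates them. `balance()` itself stays a
pure conjugate update, so the prior-recovery identity is untouched.

Posterior sampling draws the basic vector from the full posterior with
covariance scaled by `width`$^2$ and re-derives everything through the
dependency rows, so every draw is exactly Haldane/Wegscheider consistent;
`width = 0` returns the medians.

## Rate laws and simulation

Each reaction becomes a common modular rate law
$$v = u\, f_{reg}\,
\frac{k^{cat+}\prod_i (a_i/k^M_{a_i})^{h\alpha_i}
     -k^{cat-}\prod_j (b_j/k^M_{b_j})^{h\beta_j}}
     {\prod_i (1+a_i/k^M_{a_i})^{h\alpha_i}
     +\prod_j (1+b_j/k^M_{b_j})^{h\beta_j} - 1 + D_{reg}},$$
with multiplicative (allosteric) regulation
$f_{reg}=\prod_{act} \frac{x/k^M}{1+x/k^M}\prod_{inh}\frac{1}{1+x/k^M}$
and additive (specific) regulation
$D_{reg}=\sum_{act} k^M/x + \sum_{inh} x/k^M$. Design choices worth
stating:

* **Cooperativity as an exponent multiplier.** With the default
  $h = 1$ the law is exactly the classical form; for $h \ne 1$ the
  $h$-scaled exponents are the only choice under which the flux vanishes
  at thermodynamic equilibrium given the Haldane identity, so that is
  what the package implements.
* **Irreversible reactions** set $k^{cat-} = 0$.
* **One-sided (exchange) reactions** treat the absent side as an empty
  product set whose product terms are 1 — including the reverse
  numerator term $k^{cat-}\cdot 1$. Zeroing that term instead would
  break detailed balance for reversible exchanges; keeping it makes the
  flux vanish exactly where the reaction affinity does, with the implied
  external pool at unit activity.
* **Non-integer stoichiometry** is accepted as real exponents (with a
  warning); genome-scale biomass reactions need it.
* **Compartments** rescale the right-hand side:
  $dc_i/dt = (1/V_i)\sum_j n_{ij} v_j$, which conserves amounts across
  compartments of different volume.
* **Negative concentrations** (transient integrator excursions) are
  floored to zero inside the rate law.

The right-hand side is evaluated in compiled C and integrated with
`deSolve::lsoda` (defaults: rtol $10^{-6}$, atol $10^{-9}$ mM, 401
output points on $[0, 400]$ s). Pulses are discontinuities: integration
restarts at each pulse time and the stored row at that time holds the
post-pulse state. The standard perturbation experiment is a
multiplicative $\times 10$ pulse of one metabolite at 200 s; the pulse
shape and size are configurable because published protocols rarely state
them.

## Parameter gathering

Databases are *adapters*: objects declaring identifier-translation
capabilities (edges of a namespace graph) and quantity-lookup
capabilities, with synchronous query functions. Only offline
fixture-table adapters ship; a live client would plug into the same
interface. For each task (one wanted quantity of one subject, including
a $k^M$ task per reactant *and* per regulator), the search enumerates
**all simple paths** (depth-first, no namespace revisited, depth
$\le 6$, shortest first with lexicographic tie-breaks on adapter names)
from any namespace in the subject's cross-references — plus its display
name — to any adapter holding the wanted quantity, then executes every
path, following all translation branches. Every resulting record keeps
the fully resolved chain (adapter, namespace and concrete identifier per
hop) as provenance; replaying the chain against the adapters reproduces
the value. Distinct values for the same rate are all kept (the balancer
wants every measurement); only exact duplicates — same subject, quantity,
source and value via different paths — collapse.

## Model reduction

Reduction operates purely on the constraint-based view, before any
parameter work. Pruning: compute flux variability (per-reaction min/max
flux subject to $\ge 99\%$ of the FBA optimum), repeatedly delete the
unprotected reaction with the smallest variability (lexicographic
tie-break), and keep the deletion only if the reduced model's optimum
stays within 1% of the full model's and protected reactions can still
carry flux. Compression: every internal, unprotected metabolite produced
by exactly one reaction ($+p$) and consumed by exactly one ($-q$) is
eliminated by the lump $q R_1 + p R_2$, iterated so maximal linear
chains collapse; the lumped reaction is flagged synthetic so the
parameter search skips it, and the objective optimum is provably
unchanged because only flux-coupled pairs merge. Protection sets are
user input: which pathway must survive is a modelling decision, not
something the algorithm can infer. The LPs are solved by an in-package
dense two-phase simplex with Bland's anti-cycling rule — the degenerate
bases these flux polytopes produce break naive pivoting, and no
dedicated LP solver is part of the package's dependency footprint; at
the intended (toy to core-model) scale this is more than fast enough.

## The robustness protocol

To ask "how much parameter knowledge is enough?", the package builds an
idealised system where the answer is knowable: draw a full ground-truth
parameter set for a synthetic network, balance with every record, fix
the medians, and simulate the standard schedule — that trajectory is the
*gold standard*. Then repeatedly: keep a uniform random fraction of the
known records (injected as low-noise measurements, log-std $\ln 1.1$),
re-balance (the rest fall to pseudo-priors), sample full
thermodynamically consistent parameter sets from the new posterior at a
chosen width, simulate, and score the mean square error against the
reference over all species and time points. The score stream is averaged
until, after a 25-sample burn-in, its relative standard error drops
below 5%; runs that have not converged by the sample cap are flagged and
excluded from summaries, exactly as unconverged subsets are excluded in
the underlying protocol. A sample whose simulation fails (non-finite
parameters after a wild draw, or integrator breakdown) scores a sentinel
of $10^6\times$ the median successful score — dropping such samples
would bias low-information cells optimistic. With `width = 0` the
posterior collapses to its medians, so the single deterministic sample
is scored directly.

The headline summary is the smallest fraction whose median converged
score is within a factor 2 of the full-information median. On the
packaged desk-scale conditions (20 metabolites / 20 reactions) the
sufficient fraction lands at 90–100%: degraded-knowledge models are
orders of magnitude worse than full-information ones, i.e. accurate
dynamics require essentially all rates to be known to good precision —
the monotone fraction and width trends are asserted as one-sided rank
tests on a smaller (6-metabolite) system where low-information cells
still converge often enough to compare.

## The synthetic generator

The generator is the package's study condition, so its defaults are
fixed and documented rather than tuned per experiment: a spanning set of
two-metabolite reactions guarantees every metabolite participates;
further reactions connect random disjoint substrate/product sets (up to
2 and 2, unit coefficients by default to keep the ODEs mild); one-sided
reversible exchange reactions open the boundary and a repair step adds
one per metabolite that still lacks a producer or consumer, so FBA is
feasible and every species can equilibrate; regulation edges appear
independently with probability 0.05, activator or inhibitor with equal
chance; everything is a deterministic function of the seed.

Ground-truth parameters are drawn from *realistic* spreads, not from the
balancing pseudo-priors: $\mu^\circ \sim N(0, 10\ \mathrm{kJ/mol})$
(typical reaction free energies of a few kJ/mol to a few tens) and
half-width log-normal scatter ($\ln\sigma = \ln(10)/2$) around the
pseudo-prior medians for $k^M$, $k^V$, $u$, $c$. Drawing $\mu^\circ$
from the 500 kJ/mol pseudo-prior would produce equilibrium constants of
order $e^{\pm 200}$ and no simulatable gold standard; the pseudo-prior
is a statement of ignorance for inference, not a generative model of
chemistry. Fixture databases plant a chosen coverage fraction of the
truth (with log-normal noise) behind two synthetic translation hops
(`name -> dbA -> dbB`), so the path search is genuinely exercised
offline, and a bookkeeping table makes coverage exactly auditable.

What the generator does *not* emulate: scale-free genome-scale topology,
curated formation energies, realistic compartmentalisation, moiety
conservation structure (ATP/ADP pairs), or measurement biases of real
databases. Passing the robustness tests therefore shows the pipeline's
machinery is correct and its qualitative knowledge/accuracy trade-off,
not that the quantitative thresholds transfer to any particular
organism.

## Numerical choices and problem sizes

* Balancing solve: Cholesky with jitter retry ($10^{-10}$ of the mean
  diagonal); posterior covariance symmetrised.
* Residual tolerances: $10^{-9}$ (Haldane/Wegscheider),
  $10^{-10}$ relative flux at equilibrium.
* ODE: lsoda, rtol $10^{-6}$, atol $10^{-9}$ mM, max $10^4$ internal
  steps per output interval; robustness sweeps may pass a lighter
  profile through `simControl`.
* The test suite runs networks of 4–20 metabolites; the acceptance
  sweep uses the 20/20 network with 20 repetitions per fraction and a
  desk-scale sample cap of 1000 (the protocol's cap of 10000 is the
  package default; at desk scale the cap mostly determines how long
  never-converging low-information cells are allowed to run, and the
  full-information cells converge after a few hundred samples). With 20
  repetitions, fractions whose score streams rarely converge contribute
  fewer than 20 converged repetitions — they are flagged and excluded,
  matching the protocol's treatment of unconverged subsets.
* Seeds: every stochastic entry point takes an explicit seed; sweeps
  derive distinct per-cell seeds from the master seed.

## Known limitations

* Only fixture (offline) database adapters are provided; EC-number
  disambiguation, organism filtering and live clients are out of scope
  (the condition filter on pH/temperature is available but off by
  default).
* Records carrying their own temperature are not corrected to the
  system temperature; no pH/ionic-strength adjustment of equilibrium
  constants is attempted.
* Cooperativity is a fixed constant per reaction, never estimated.
* Alternative rate laws (mass action, power laws) and dynamics-aware
  reduction are not implemented.
* The exchange-reaction convention (implicit external pool at unit
  activity) makes one-sided reactions thermodynamically well defined but
  is a modelling convention, not physics.
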