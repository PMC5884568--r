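---
title: "Modelling two-locus underdominance and killer-rescue gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-locus underdominance and killer-rescue gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivedyn)
```

## The systems being modelled

Two-locus engineered underdominance (UD) and killer-rescue (KR) are
genetics-based vector-control strategies built from two independently
inherited transgenic constructs (here called A and B) inserted at unlinked
autosomal loci.  In UD, each construct carries a lethal element, a
suppressor of the *other* construct's lethal, and a cargo gene (for example
a virus-refractoriness trait): individuals inheriting one construct without
the other are non-viable, which selects for carrying both or neither and
makes the system threshold-dependent and self-sustaining.  In KR, construct
A carries only a killer and construct B its rescue plus the cargo:
the rescue is favoured while the killer is common, rises transiently, and
the whole system is then eliminated by its fitness costs — it is
self-limiting.

With two loci and up to two copies per locus there are nine genotypes,
indexed $i = 3\eta_{iA} + \eta_{iB} + 1$ where $\eta_{iA}, \eta_{iB} \in
\{0,1,2\}$ are the construct copy numbers (`genotype_table()`).  Whether a
genotype is killed depends on the drive class and on whether one suppressor
copy rescues two lethal copies ("strong suppression") or two copies are
needed ("weak suppression"); `lethality()` tabulates the $\gamma_i \in
\{0,1\}$ values per sex (lethality can be bisex or female-specific).
Incomplete penetrance ($0 < \gamma < 1$) is deliberately out of scope and
rejected at validation.  Total relative fitness is multiplicative across
copies,
$$\Omega_i^{M,F} = \epsilon_A^{\eta_{iA}}\,\epsilon_B^{\eta_{iB}}\,
(1 - \gamma_i^{M,F}),$$
with $\epsilon_A, \epsilon_B \in [0,1]$ the relative fitness per copy.  A
`"none"` system (no lethal elements) is provided as a neutral control for
conservation checks.

## Population dynamics

The continuous-time model tracks adult males $M_i(t)$ and females $F_i(t)$
of each genotype in a panmictic population with continuous reproduction, a
1:1 primary sex ratio, and a fixed egg-to-adult development delay $\tau$.
Egg production is female-limited and male genotypes contribute as
frequencies:
$$v_i(t) = w_i(t) = \sum_k F_k(t) \sum_j \frac{M_j(t)}{\sum_m M_m(t)}
\, P(i \mid \text{father } j, \text{mother } k),$$
so each female contributes one male-egg unit and one female-egg unit per
unit time, and $\sum_i v_i = \sum_i w_i = \sum_k F_k$.  This normalisation
is forced by consistency with the model's wild-type steady state
$N^* = \frac{1}{\alpha}\left(\frac{\rho}{\mu} - 1\right)^{1/\beta}$:
any other per-female scaling shifts the equilibrium away from $N^*$
(the package tests integrate a wild-type population and require convergence
to $N^*$ to 0.1%).  The inheritance kernel $P$ is the Mendelian two-locus
cross with unlinked loci (`cross()`), checked in the tests against an
independent brute-force gamete enumeration.

Recruitment passes through density-dependent larval competition of
Maynard Smith–Slatkin form.  With early-acting fitness/lethal effects
(acting in eggs or early instars, before competition):
$$\frac{dM_i}{dt} = \frac{\rho\, v_i(t-\tau)\,\Omega_i^M}
{1 + \left(\sum_{i} \alpha\,[v_i(t-\tau)\Omega_i^M +
w_i(t-\tau)\Omega_i^F]\right)^{\beta}} - \mu M_i(t),$$
and analogously for females.  With late-acting effects (in pupae or pharate
adults, after competition but before mating) the $\Omega$ terms are removed
from the denominator only: dead-to-be larvae still competed.  This single
difference drives the large gap in achievable population suppression
between the two timings: late-acting deaths cannot be compensated by
relaxed competition.

The two-deme model duplicates the system and couples demes by continuous
un-delayed exchange, adding $\psi(X_i^{\mathrm{other}} -
X_i^{\mathrm{own}})$ to every equation; $\psi = 0$ recovers independent
demes.  Both demes share one parameter set (equal-sized populations); the
exchange terms are antisymmetric, so migration conserves instantaneous
totals.

### Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $\alpha$ | density parameter; carrying capacity $\propto 1/\alpha$ | 0.02 | — |
| $\beta$ | strength of density-dependent larval competition | 1.1 | — |
| $\rho$ | per-capita growth rate | 1.01 | d$^{-1}$ |
| $\mu$ | adult mortality | 0.12 | d$^{-1}$ |
| $\tau$ | egg-to-adult delay | 18 | d |
| $\theta$ | release ratio, introduced/wild | 1 | — |
| $\psi$ | migration rate | 0–0.01 | d$^{-1}$ |
| $\epsilon_{A,B}$ | relative fitness per construct copy | scanned | — |

The defaults give $N^* = 309.08$ adults; $\alpha = 0.7$ gives 8.83.  The
value of $\beta$ sets the dynamic regime after perturbation: stable
monotone/weakly damped dynamics at 1.1, damped oscillations at 2.75,
sustained (neutral) oscillations at 3.5.  Percentage trajectories are
invariant to $\alpha$: rescaling $\alpha$ rescales all counts by the same
factor, which the tests verify to $10^{-6}$ relative.

## Releases and initial conditions

A release introduces $\theta N^*$ adults of genotype AABB at $t = 0$ into
the target deme: bisex releases split 1:1 male:female; male-only releases
introduce $\theta N^*$ males by default (the release ratio is defined
against all wild adults; scaling against wild males only, $\theta N^*/2$,
is available as an option since either reading of a sex-unqualified ratio
is defensible).

The constant initial function supplied to the integrator for $t \le 0$
*includes* the released adults.  This is a deliberate modelling choice: the
released adults are present and mating from the moment of release, so their
progeny must begin to emerge at $t = 0$, not at $t = \tau$.  Were the
pre-release history wild-type only, every released cohort would decay by
$e^{-\mu\tau} \approx 0.115$ before producing a single recruit, the
effective introduction frequency of a 1:1 release would drop from 0.5 to
about 0.10, and the UD system would fail to drive at fitness values where
the corresponding discrete-generation model (and the package's own
threshold results) show clear introgression.  With the inclusive history
the delay-model and discrete-model thresholds agree to within the 0.01
fitness grid used throughout.

## Numerical integration

The delay equations have one constant delay, non-stiff dynamics at the
default parameters, and derivative discontinuities only at the release time
and its images $t = k\tau$.  They are integrated by the method of steps
with classical fixed-step RK4 and cubic Hermite dense history: the step is
the largest value not exceeding `max_step` that divides $\tau$ exactly, so
every breakpoint falls on a mesh point and the delayed lookup
$t - \tau$ always lands in completed history.  A single fixed-step scheme
is bitwise deterministic and makes step-halving a direct error check; the
tests verify that halving `max_step` leaves extracted metrics unchanged to
well below reporting precision, and an independent `deSolve` integration of
the pre-$\tau$ segment (where the lagged state is the constant history)
agrees to $10^{-7}$.

`max_step` defaults to 0.05 d: the depth and timing of transient population
minima are the quantities most sensitive to the mesh, and 0.05 d resolves
them to well inside the tolerances used for any reported number.  Counts
are clamped at zero only inside the offspring-pool kernel (to guard
vanishing interpolation noise near extinction); the integrator itself does
not clip, and aborts if any state falls below `-nonneg_tol` (default
$10^{-6}$) or becomes non-finite, since the model preserves positivity and
negativity signals a numerical fault.

## Metrics and criteria

`drive_metrics()` reads per-deme summaries over $t \ge 0$: population and
wild-type-female extrema, peak percentage suppression relative to $N^*$ and
its timing, final-state ("equilibrium") suppression, and transgene
frequency extrema.  Transgene frequencies are allele frequencies among
adults, $\sum_i \eta_{iX}(M_i + F_i) / 2N$; the overall frequency averages
the two constructs and the KR "rescue" frequency is the construct-B
frequency.  Equilibrium quantities are read from the final state of a long
run (5000 d for threshold decisions) rather than by fixed-point solving,
because the oscillatory $\beta$ regimes have no point equilibrium.

Two success criteria needed care:

* **UD lasting introgression.**  The release outcome is bistable: the
  final overall frequency settles either near 0 or at a high internal
  equilibrium.  Just above threshold that equilibrium is about 0.89 — not
  1 — because strong suppression leaves some viable heterozygote classes
  segregating.  The bisection criterion is therefore final frequency
  > 0.5, the midpoint separatrix far from both attractors; 0.95 would
  misclassify near-threshold introgression as failure.  Outcome *labels*
  ("eliminated" < 0.01, "fixation" > 0.95, else "intermediate") are kept
  separate from this decision rule, since the two-deme intermediate regime
  genuinely sits between the cutoffs.
* **KR drive condition.**  "The rescue frequency increases" is tested as a
  rising segment, $\max_t\,(B(t) - \min_{s\le t} B(s)) > 10^{-4}$, not as
  exceeding the value at release: the multiplicative cost is paid from the
  first generation, so near threshold the rescue frequency dips before the
  killer-driven rise, without necessarily re-crossing its starting value.
  The tolerance guards integration noise.  This reading also restores the
  expected ordering of thresholds (KR below UD, weak suppression above
  strong within each class).

## The discrete-generation comparator

`discrete_step()` iterates the classical population-genetics recursion:
random union of gametes weighted by parental genotype frequencies, then
viability selection by $\Omega_i^{M,F}$, then renormalisation
(selection-before-census), tracked per sex.  It shares only the cross
kernel with the delay model and serves as an independent route to the same
thresholds; `discrete_fitness_threshold()` and `find_fitness_threshold()`
agree within the 0.01 fitness grid for the UD system at a 1:1 release.
Note that one neutral generation restores Hardy–Weinberg proportions per
locus but not jointly: linkage disequilibrium between the (unlinked) loci
decays geometrically rather than instantly, so the joint-HW fixed point is
only tested from linkage-equilibrium parents.

## Problem sizes used in the tests and scripts

Fitness scans step $\epsilon_A = \epsilon_B$ by 0.01 over $[0,1]$ (101
runs per system/timing) with `t_end = 5000` d and `max_step = 0.05` d, the
horizons at which equilibrium metrics are converged to well below their
reporting precision; threshold bisections run to a fitness tolerance of
$10^{-3}$.  Unit tests use shorter horizons (a few hundred days) and a
coarser 0.25 d step, which the step-halving checks show is already
accurate for qualitative assertions.

## What the model does and does not capture

The model is deterministic and demographically smooth: no stochasticity,
drift or Allee effects, so very small populations are outside its remit.
It assumes no mutation, no resistance alleles, no transgene separation and
no sex linkage; adults mate every day with no sperm storage; density
dependence acts only among larvae born at the same instant (a limitation
of the fixed-delay formulation); and the two-deme geometry is two panmictic
points with symmetric exchange, not a spatial continuum.  Conclusions
drawn from passing tests therefore concern the idealised dynamics;
real-population features such as seasonality, age structure within the
delay, or spatially structured dispersal are deliberately not represented.
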