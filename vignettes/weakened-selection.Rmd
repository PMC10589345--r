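---
title: "Weakened selection under a natural enemy: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakened selection under a natural enemy: models, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`enemyfix` studies the fate of a host mutant whose fitness has nothing to do
with an SI-type pathogen that attacks wild-type and mutant hosts alike.
This vignette is the package's own account of the science: the three model
levels and their assumptions, the parameters that matter, every numerical
convention a reader might need to reproduce or audit a result, and what the
desk-scale test conditions do and do not demonstrate.

## The question

In a constant, well-mixed population the Moran process gives the fixation
probability of $i$ mutants with selection coefficient $s$ among $n$
individuals:

$$P_{fix}(i) = \frac{1 - (1+s)^{-i}}{1 - (1+s)^{-n}}.$$

A population coexisting with a pathogen also fluctuates around a stable
size, so one might expect Moran-like behavior with $n$ set to the mean
uninfected population $N_u$.  Spatially explicit simulation says otherwise:
when infection is fast, hosts persist only through a refuge effect — local
extinctions balanced by expansion into transiently pathogen-free space —
and wild-type and mutant hosts end up spatially segregated.  Competition
then happens between patches rather than individuals, and selection on the
mutant is strongly weakened in both directions.

## Level 1: the lattice agent-based model

Sites of an $n_1 \times n_2$ toroidal grid (Moore/8-neighborhoods, periodic
in both axes, 0-based row-major coordinates internally) are empty or hold
one cell: uninfected or infected, wild-type or mutant.  A *time-step* is
$N_1$ *elementary updates*, where $N_1$ is the number of occupied sites
**frozen at the step boundary**; each update picks a site uniformly among
the sites occupied at the moment of the pick, *with replacement*.  These
two conventions (freeze $N_1$, pick with replacement) are the simplest
consistent reading of "one update per currently occupied site"; the
alternative (recomputing $N_1$ within the step) changes nothing at
quasi-equilibrium, where $N_1$ moves by $O(\sqrt{N_1})$ per step.

Per pick, one uniform variate $u$ decides the event:

* uninfected cell: $u < p_{div}$ → division attempt
  ($p_{div} = R$ for wild-type, $R(1+s)$ for mutants);
  $p_{div} \le u < p_{div} + D$ → death; otherwise nothing.
* infected cell: $u < B$ → infection attempt; $B \le u < B + A$ → death;
  otherwise nothing.

Division places a same-genotype uninfected offspring on a uniformly chosen
Moore neighbor and **fails silently** when that neighbor is occupied (no
displacement, no retry): crowding is what makes the dynamics logistic.
Infection succeeds only when the chosen neighbor holds an uninfected cell
(of either genotype).  Infected cells never divide or recover; their
genotype label is retained for bookkeeping only and has no dynamical
effect.  The documented variate partition is exposed through
`abm_elementary_update()`, so every rule can be exercised with forced
draws.

Probability budgets $R(1+s) + D \le 1$ and $A + B \le 1$ are validated at
construction and never clamped — a configuration that violates them is a
user error, not a boundary case.

**Initial condition.**  Runs start from a centered square block of
uninfected wild-type cells (side $\lfloor \min(n_1,n_2)/2 \rfloor$ by
default) with a smaller infected block (side
$\max(2, \lfloor \text{outer}/5 \rfloor)$, present only when $B > 0$)
overwriting its middle.  The long-run state does not depend on this choice;
the defaults just reach quasi-equilibrium quickly.

**Equilibrium measurement.**  $N_u$ is the temporal mean of the uninfected
count over a window after burn-in; defaults are 500 and 5000 time-steps.
At the reference parameters ($R = 0.5$, $D = 0.05$, no infection, 32×33)
this gives $\approx 949$, within half a percent of both the site-balance
mean-field value $n_1 n_2 (1 - D/R) = 950$ and the reference operating
point of this configuration.

**Grid calibration.**  Faster infection depresses $N_u$, so comparisons
across infection rates enlarge the grid until $N_u$ returns to a common
target (`abm_calibrate()` measures candidate grids and picks the closest).
The exact grid-size-to-$B$ association is not critical; what matters is
holding $N_u$ approximately constant so the Moran reference is common.

## Level 2: the stochastic deme model

$\mathcal{N} = n_1 n_2$ patches, each well-mixed, evolve by an exact
Gillespie algorithm whose per-patch rates mirror the patch ODEs: logistic
division $r x_i (1 - (x_i + y_i + z_i)/K)$ (and $r(1+s) y_i (\cdot)$ for
mutants), deaths $d x_i, d y_i$, mass-action infection
$\beta x_i z_i, \beta y_i z_i$, infected death $a z_i$, and per-capita
migration at rate $\mu$ for every individual.  Numerical conventions:

* Division rates are clamped at zero when a patch exceeds $K$ (stochastic
  fluctuations can overshoot); the rates match the ODE only in the feasible
  region, which is where the system lives.
* Non-spatial migration sends the migrant to a uniformly chosen patch
  *including the source* (a self-migration is a no-op event).  This exactly
  reproduces the ODE migration term
  $\mu(\sum_k x_k / \mathcal{N} - x_i)$ in mean.
* Spatial migration is uniform over the 8 Moore-neighbor patches with
  periodic wrap, consistent with the lattice model's boundary conditions.
* Infected individuals carry no genotype ($z_i$ is a single pool); mutant
  lineage extinction is judged on the uninfected mutant total alone.
* The implementation is exact (no tau-leaping): per-patch total rates are
  cached, updated after each event, and the global total is refreshed
  exactly every 8192 events to stop floating-point drift.

At the reference parameters ($r = 0.7$, $d = 0.1$, $K = 100$, $\mu = 0.02$,
no infection, 11×12 patches) the time-weighted mean total uninfected
population is $\approx 11{,}288$ — marginally below the independent-patch
value $132 \cdot K(1 - d/r) = 11{,}314$ because demographic noise interacts
with the concave logistic birth rate — matching the reference operating
point of this configuration.

## Level 3: coarse-grained patch competition

When infection is fast, patches rarely contain both genotypes, and the
dynamics can be summarized by counts of wild-type ($X$), mutant ($Y$) and
infected ($Z$) patches with mean per-deme loads $w_x, w_y, w_z$.  The ODEs
(implemented in `integrate_coarse()`, solved with deSolve's embedded
Runge–Kutta 4(5) pair at relative tolerance $10^{-8}$ with non-negativity
projection of the sampled trajectory) contain four processes: colonization
of empty patches, patch infection, patch conversion, and infected-patch
extinction on a timescale $T_{ext}$.

Two patch-level selection coefficients emerge:

* $s_p^{conv}$, the bias of the conversion process.  The package's default
  reads it off the ratio of the conversion fluxes,
  $s_p^{conv} = (w_y P_{x\to y})/(w_x P_{y\to x}) - 1$.  This definition is
  **an implementation choice, flagged as pluggable**: conversion through
  death–birth events is the same process that yields the ordinary Moran
  dynamics, but no closed form for it is fixed by the model statement, so
  any externally derived value can be supplied directly to `s_patch()`.
* $s_p^{ext-rec} = \dfrac{w_y P_{col}^y P_{inf}^x}{w_x P_{col}^x P_{inf}^y} - 1$
  with $P_{col} = 1 - d/r$ (branching-process survival of a founding cell)
  and $P_{inf} = 1 - a/(w\beta)$ (survival of a founding infected cell,
  clamped to 0 below the invasion threshold $w\beta \le a$).  For a 2%
  cell-level division advantage at the reference deme parameters this
  evaluates to $\approx 0.0065$ — a three-fold compression of selection,
  the quantitative heart of the weakening effect.

The overall coefficient is the rate-weighted mean
$s_p = (R_{ext\text{-}rec}\, s_p^{ext-rec} + R_{conv}\, s_p^{conv}) /
(R_{ext\text{-}rec} + R_{conv})$, and the take-over probability of $i$
mutant patches among $X_{eq}$ is the Moran formula applied at patch level.
`estimate_event_rates()` provides default $R_{conv}, R_{ext\text{-}rec}$
read off the corresponding ODE fluxes at equilibrium, again with a
user-override because their exact derivation is model-dependent; the
package deliberately treats $w_*, T_{ext}, P_{x\to y}, P_{y\to x}$ as
inputs (measurable from the deme module) rather than re-deriving them.

The coarse model describes non-spatial migration only; it is an explanatory
approximation, not a replacement for the stochastic engines.

## The fixation-trial protocol

1. Burn the mutant-free system in (defaults: 500 lattice steps / 100 time
   units; trials in this package use 400 steps at desk scale, which the
   equilibrium series show is ample for grids up to 40×40).
2. Arm a trigger: introduce mutants at the first moment the uninfected
   count equals $\text{round}(N_u)$.  Because counts move by ±1, equality
   is normally hit quickly; if it is not hit within a waiting window
   (default 5000 steps / 2000 time units), the protocol falls back to the
   closest approach seen during that window, and after twice the window it
   introduces immediately.  The fallback exists for robustness; in all
   test conditions the exact trigger fires.
3. Introduce $i$ mutants: on the lattice, $i$ uninfected wild-type sites
   chosen uniformly without replacement are converted simultaneously; in
   the deme model, $i$ repetitions of (pick a patch proportionally to its
   wild-type count, convert one individual).
4. Run to absorption on **uninfected-class counts only**: extinction when
   no uninfected mutants remain, fixation when no uninfected wild-types
   remain (with mutants present), global extinction when neither remains.
   Infected cells are destined to die and cannot re-found a lineage, so
   stopping at uninfected-wild-type $= 0$ does not change the absorbing
   outcome; it does shorten runs, and conditional times are measured to
   this declaration — a convention, since the alternative (waiting for the
   last infected wild-type to die) adds a small additive term.
5. Censor at a horizon (default $10^6$ steps/time units).  Censored runs
   are excluded from the denominator when they exceed 0.1% of runs,
   otherwise counted as non-fixations with a warning; global extinctions
   count as non-fixations but are reported separately.  A sweep aborts if
   more than half the trials die before introduction — that signals a
   non-persistent parameter regime, not sampling noise.

Estimates use the Wilson score interval for the "95% confidence limits"
(Clopper–Pearson available behind a flag); the interval method is a
packaging choice, made because Wilson behaves well at the small counts
fixation experiments produce.  Conditional fixation times are averaged over
fixation runs only.

Reproducibility: each trial owns a PCG32 stream keyed by
`seed_base + replicate index` (streams within a trial are separated by
fixed stream constants), so any single trial can be re-run bit-exactly from
its recorded seed, independent of the others.

## Study conditions at desk scale, and what they show

The test suite runs the full-scale equilibrium measurements (32×33 lattice,
11×12 patches) but performs fixation experiments at reduced scale, chosen
once as follows:

* **No-infection arm:** 20×20 lattice, $N_u^* \approx 360$.  Small enough
  that 4000–5000 trials complete in minutes, large enough that
  $1/N_u^*$-scale probabilities are resolvable.
* **High-infection arm:** $B = 0.5$.  On grids much below ~30×30, faster
  infection ($B \gtrsim 0.7$) frequently destroys the whole population or
  loses the pathogen — the refuge effect needs room — while much slower
  infection ($B \lesssim 0.3$) loses the pathogen to stochastic fade-out on
  a large fraction of runs.  $B = 0.5$ on a ~36–40 square grid keeps the
  pathogen endemic across seeds while leaving a clear contrast to $B = 0$.
  The infected grid is calibrated at test time to the no-infection
  $N_u^*$.
* Trial counts: 5000 (neutral), 4000/3000 (Moran agreement), 1500/800 per
  arm (trends); selection coefficients $s \in \{0.02, 0.05, -0.01\}$ with
  $i \in \{1, 20, 100\}$ mutants, sized so the expected number of fixations
  per arm is tens to hundreds.
* Deme fixation runs use 2×2 patches with $K = 50$ ($N_u^* \approx 171$) —
  the smallest system in which migration still matters.

These conditions demonstrate the *directional* results — neutral fixation
at $i/N_u$ regardless of infection, Moran agreement without infection,
reduced (increased) fixation of advantageous (disadvantageous) mutants
under infection, shortened conditional times — each with one-sided tests at
95%.  They do **not** reproduce full-scale effect magnitudes obtained at
larger scale (e.g. fixation-probability shifts of up to three orders of
magnitude for disadvantageous mutants, which require population sizes near
$10^3$–$10^4$ and very many replicates), and the trend experiments run on
the lattice engine only; the deme engine's protocol is exercised without
infection, where its Moran agreement is verified.  Nothing in the generator
is tuned per-test: the engines' defaults are the model definitions above.

What the synthetic dynamics also do not emulate: real host–pathogen systems
have recovery or immunity (SIR/SIRS), vertical transmission, recurrent de
novo mutation, co-evolving pathogens, and non-periodic habitat boundaries —
all outside this package's scope.  Passing tests show the models behave as
specified, not that any particular biological system does.

## Known limitations

* The lattice engine's within-step dynamics make "time" discrete and
  slightly anisotropic at the single-step scale; all reported times are in
  time-steps and only comparisons between arms are meaningful.
* The coarse model's $s_p^{conv}$, $R_{conv}$ and $R_{ext\text{-}rec}$
  defaults are documented reading conventions of the ODE terms, not derived
  quantities; use the override arguments when an external derivation is
  available.
* `deme_equilibrium()` and the trial trigger use *total* uninfected counts;
  with $\mu = 0$ and many patches, patches decouple and the global trigger
  can hide per-patch excursions.  Use `deme_run()`'s per-patch state for
  patch-level diagnostics.
* Single-patch (non-spatial) systems with fast infection go extinct — this
  is expected SI behavior and the reason the models are spatial; the
  persistence-failure diagnostics treat it as a configuration problem, by
  design.
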