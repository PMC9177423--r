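---
title: "Modelling lifelong clonal dynamics in blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifelong clonal dynamics in blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaldyn)
```

`clonaldyn` analyses the kinetics of clonal haematopoiesis — the
expansion of mutant haematopoietic stem cell (HSC) clones — from two
data types: serial variant allele fraction (VAF) measurements in
late life, and time-calibrated phylogenies of single-cell-derived
blood colonies that reach back to embryogenesis. This vignette is
the package's account of the models, the choices behind them, and
what the bundled synthetic data can and cannot establish.

## The longitudinal growth model

Each mutation is assumed heterozygous and private to one clone, so
its VAF is half the clone's cell fraction and successive VAFs of one
mutation track one clone. For clone $c$ observed at ages $t$:

$$\mathrm{alt}(t) \sim \mathrm{BetaBin}\!\left(\mathrm{depth}(t),\,
  \alpha(t),\, \beta\right),\qquad
  \alpha(t) = \frac{\beta\, q(t)}{1 - q(t)},$$

$$q(t) = \mathrm{ilogit}\!\left(
  (b_{\mathrm{gene}} + b_{\mathrm{site}} + b_{\mathrm{clone}})\, t
  + u\right).$$

The logistic form encodes exponential growth that saturates as the
clone fills the compartment; Wright–Fisher simulations with constant
fitness produce exactly this shape (the per-generation map
$f' = f(1+s)/(1+fs)$ advances $\mathrm{logit}(f)$ by
$\log(1+s)$ each generation, which the test suite verifies).
Growth decomposes hierarchically:

* `b_gene` (prior $N(0, 0.1)$, units 1/yr on the logit scale): the
  driver gene's average effect. Genes carrying both truncating and
  missense mutations get one effect per class (`GENE:T`, `GENE:M`).
* `b_site` (prior $N(0, 0.1)$): an extra effect for *recurrent*
  sites — missense sites mutated in at least two individuals
  (`recurrent_min_individuals`). A gene whose mutations all sit on
  one recurrent site is modelled at site level only; otherwise the
  gene and site effects would be a pure sum with no data to split
  them.
* `b_clone` (prior $N(0, 0.05)$): clone-specific "unknown-cause"
  growth — the residual after the driver's identity.
* `u`: a per-clone offset in the age-0 (birth) frame that encodes
  when the clone arose. Its prior is a wide normal, default
  $N(-15, 15)$. The width matters: a clone growing at 0.5/yr and
  first detected at age 60 implies $u \approx -35$, and a tight
  prior on $u$ leaks into systematic shrinkage of fast clones'
  growth rates (we observed exactly this failure with an SD of 5,
  which is why the default is wide).
* `beta`: a single cohort-wide technical overdispersion with prior
  $N(\mu_{od}, \sigma_{od})$ truncated to positive values, whose
  hyperparameters come from replicate sequencing (below).

`q(t)` saturates at 1 as written, although a heterozygous sweep
caps VAF at 0.5. We implement the formula as written (default
`vaf_ceiling = 1`) and expose `vaf_ceiling = 0.5` as the
biologically motivated variant; the onset algebra folds the ceiling
into `u` so both parameterizations back-extrapolate consistently.

### Sampling

Posteriors are drawn by an adaptive Metropolis-within-Gibbs sampler
on the exact marginal beta-binomial likelihood (defaults: 5,000
iterations per chain, half discarded as warm-up, two chains). Two
reparameterizations make this mix well where naive single-site
updates stall:

1. **Centering.** Per-clone parameters are sampled as the value of
   $\mathrm{logit}\,q$ at the clone's mean observation age plus a
   slope, decorrelating slope and intercept (observation ages of
   55–80 years put the age-0 intercept far outside the data).
2. **Ridge moves.** The likelihood constrains only the sums
   $b_{\mathrm{gene}} + b_{\mathrm{clone}}$ (and site analogues), so
   the joint posterior has a prior-limited ridge. A dedicated move
   proposes $b_{\mathrm{gene}} \mathrel{+}= \delta$,
   $b_{\mathrm{clone}_c} \mathrel{-}= \delta$ for all member clones
   simultaneously; it leaves the likelihood and the offsets exactly
   invariant and is accepted on the prior ratio alone, which lets
   the sampler slide along the ridge freely.

Proposal scales adapt by Robbins–Monro only during warm-up (target
acceptance 0.44), so the kept draws come from a fixed kernel.
Convergence is monitored by split R-hat across chains on all growth
parameters and the overdispersion; values above 1.05 produce a
warning carrying the offending parameters, never a silent pass. In
the test suite a single-clone posterior is cross-checked against
deterministic three-dimensional grid integration over
$(b, u, \beta)$, a route entirely independent of the sampler.

### Overdispersion calibration

Replicate designs share one true VAF within each group. In a
*dilution* series the group VAFs are known by design
(0.05, 0.02, 0.01, 0.005, 0), so they are fixed and only
$\beta = e^r$ (with $r$ unconstrained and no prior) is inferred;
this sidesteps the incidental-parameter bias that appears when two
or three replicates must also estimate their own mean. Verified
wild-type groups are excluded exactly — a zero VAF produces zero
counts with probability one and carries no dispersion information.
In *triplicate* mode (cohort samples at unknown VAFs) each group
receives a free logit-mean; with $k = 3$ this is mildly
conservative (biased toward less overdispersion), the safe
direction for a quantity used as a prior. The posterior mean and SD
of $\beta$ over at least 1,000 draws become
$(\mu_{od}, \sigma_{od})$.

### Outliers and fixed-rate growth

Each observation is scored by its posterior-averaged two-sided
beta-binomial tail probability (inclusive tails, averaged over
posterior draws); a tail below 2.5% flags an outlier, and a clone
with no outliers is growing at a fixed exponential rate. We read
the threshold as two-sided at 2.5% per tail; a one-sided reading
exists but halves the nominal type-I rate, and the calibration test
(about 5% of observations flagged when data are regenerated from
the fitted model) pins the two-sided interpretation. The
cohort-level fixed-rate proportion carries a Jeffreys
beta-distributed confidence interval.

## Age at clonal onset

A fitted trajectory is back-extrapolated under a two-phase
Wright–Fisher growth model in an HSC compartment of $n$ cells with
$g$ generations per year (defaults 50,000 and 2; onset estimates
are insensitive across $n$ of 10,000–600,000 and $g$ of 1–20,
which the tests check as smoothness):

$$t_0 = \frac{\log(1/n) - u}{b},\qquad
  t_{0,\mathrm{adj}} = t_0 + \frac{\log(g/b)}{b} - \frac{1}{b}.$$

The adjustment first finds when the clone entered deterministic
growth and then subtracts the expected time a surviving clone
spends escaping drift. It is undefined for $b \le 0$ (a typed
error). Onsets are *feasible* if they fall after conception, taken
as age $-1$ year for the feasibility bound; the tree calibration
uses $-0.75$ for gestation, and both constants are arguments.
Posterior uncertainty is propagated by applying the closed forms to
every posterior draw with $b > 0$ (the fraction of non-positive
draws is reported per clone) and summarizing by median and HPDI.

Two derived quantities follow. *Detection latency* is the time from
$t_{0,\mathrm{adj}}$ until the trajectory crosses a detection
threshold (default VAF 0.2%). *Minimal historical growth* asks, for
a clone whose observed rate projects its onset before conception,
how fast it must have grown over a whole lifetime to reach its
current VAF: we solve $t_{0,\mathrm{adj}}(b) = -1$ with
$u(b) = \mathrm{logit}(q_T) - b\,T$ by bisection to $10^{-6}$.
The solve is deliberately post hoc on the fitted terminal VAF
rather than a re-run of the MCMC under constraint — it is
deterministic, testable against a grid search, and separates the
measurement (the fit) from the extrapolation. One numerical trap is
handled explicitly: $t_{0,\mathrm{adj}}(b)$ is not monotone, since
the drift correction $\log(g/b)/b$ diverges as $b \to 0$ and makes
vanishing rates spuriously "feasible"; the bisection therefore
brackets the biologically relevant upper crossing of the infeasible
region on a log grid first.

## Phylodynamics of colony trees

Colony phylogenies arrive with branch lengths in somatic mutation
counts. Calibration to time divides lengths by the variant-calling
sensitivity, makes the tree ultrametric by proportional per-tip
path stretching (each node is placed at the mean, over its
descendant tips, of its fractional root-to-tip position, scaled to
the mean tip depth — the bespoke normalization used on real data is
unpublished, so we use the simplest proportional scheme and isolate
it in one function), and maps the molecular axis in two phases: the
first 55 mutations span conception ($-0.75$ yr) to birth, the rest
scale linearly to the age at sampling. Trees whose sampled colonies
all descend from one expanded clone keep the pre-MRCA trunk as a
root edge so the birth anchor remains correct.

Expanded clades are sets of colonies sharing an MRCA, detected when
a driver is annotated on the MRCA's stem branch or the stem spans
more than 10% of the tree depth with at least 5 tips; only maximal
clades are reported, and the stem's endpoints bound the clonal
onset. "Depth" is time depth after calibration by default, with a
`depth_measure = "molecular"` switch since the convention is
ambiguous on real data.

Effective population size is reconstructed by a classic/generalized
coalescent skyline rather than a Gaussian-process phylodynamic
model: for an inter-coalescent interval with $k$ lineages and
duration $\Delta t$ years, $\hat N_{\mathrm{eff}} = k(k-1)\Delta
t/2$ in HSC × years (population size times generation time), with
adjacent intervals pooled until each pool spans
`smoothing_epsilon` years. The skyline is transparent,
dependency-free, and testable against independent coalescent
simulations (constant-size recovery within a factor of two and
exponential-growth-rate recovery within 25% are acceptance checks);
a GP-based estimator could be plugged in behind the same
trajectory contract. Each pooled point carries the log-scale
variance of the exponential-interval model,
$\mathrm{trigamma}(m)$ for $m$ pooled coalescences, and a
high-variance flag at $\log(\mathrm{var}) > 5$. With $m \ge 1$
that variance is bounded, so the flag rarely fires for the
closed-form skyline; it exists for externally supplied trajectories
whose variance explodes in data-poor regions, and flagged points
are excluded from all downstream fits.

Biphasic growth is fitted as continuous two-segment least squares
on $\log N_{\mathrm{eff}}$ versus time, the breakpoint chosen by
grid search over interior trajectory times with at least two points
per segment and ties broken to the earliest candidate (noiseless
two-segment inputs are recovered exactly when the breakpoint lies
on the grid). Deceleration is quantified two ways: the *size ratio*
compares the clonal fraction scaled by a carrying capacity (default
200,000 HSC × years) with the early-rate extrapolation to the
sampling age, computed in log space to avoid overflow; and the
*growth ratio* divides the late biphasic rate by the growth
coefficient of a logistic fit to the trajectory at that fixed
capacity, so that saturation alone does not masquerade as
deceleration.

## What the synthetic data emulate

`simulate_wf()` is an exact multinomial Wright–Fisher resampler
(not a diffusion approximation): each generation, $n$ cells are
redrawn with a driver clone's offspring weighted by $1+s$; clones
arise as single cells at set generations, and an optional
mid-life fitness change supports deceleration scenarios. Defaults
are the analysis constants: 50,000 HSCs, 2 generations/year.
`sample_sequencing()` reads a history at scheduled ages with
beta-binomial noise; `simulate_cohort()` draws cohorts directly
from the hierarchical model (elderly cohort conditions: ages 55–81,
4–6 timepoints over about 16 years, depths near 1,700×,
first-observation VAFs of 0.5–10%, overdispersion 100 — depths and
window mirror a longitudinal ageing cohort, and the overdispersion
is a realistic mid-range choice since no public value exists).
`sample_colony_tree()` draws colonies from the final generation and
builds their genealogy by a backward within-clone coalescent
through the recorded population sizes, with a doubling embryonic
phase back to a single cell at conception, Poisson mutations at
18/year after birth and 55 expected before it.

Two things the generator deliberately does not emulate: real
cohorts mix clones within individuals with possible phasing and
copy-number changes (the model assumes one heterozygous mutation
per clone, as does the analysis), and colony trees come without
variant-calling error beyond the sensitivity scaling (no artefact
branches, no missing mutations). Passing tests therefore establish
internal consistency of the method under its own assumptions —
generative recovery, calibration, and cross-route agreement — not
robustness to the artefacts of real pipelines.

## Numerical choices and degenerate inputs

* Logit arguments are clamped to $\pm 30$ globally and $\pm 12$
  inside the likelihood, where extreme concentrations would lose
  precision in `lbeta`; the posterior mass there is negligible
  under the study conditions.
* Beta-binomial tails are summed over the shorter side of the
  distribution, so an observation costs
  $O(\min(x, \mathrm{depth} - x))$.
* The HPDI is the shortest window over the sorted draws containing
  $\lceil \mathrm{mass} \cdot n \rceil$ points; among tied windows
  the earliest wins.
* Clones with all-zero counts are fitted (growth pulled to the
  prior) and flagged `uninformative`; clones with fewer than two
  timepoints, non-increasing ages, or counts exceeding depth are
  rejected with named errors.
* `run_pipeline()` derives every stage seed from one master seed
  and records them in a manifest; identical configuration and seed
  reproduce byte-identical tables.

Problem sizes in the test suite are chosen to make each check
sharp but quick: 60-clone cohorts at the model's default 5,000
iterations for recovery and calibration, 40–50 replicate trees for
the coalescent oracles, 96-colony trees for the end-to-end round
trip, and 200 replicates for the noisy biphasic fits.

## Known limitations

* One driver per clone; nested subclones and interclonal
  competition beyond the shared carrying capacity are out of scope.
* The skyline's pointwise uncertainty is cruder than a GP
  posterior; derived ratios inherit single-tree noise, which
  dominates the growth-ratio spread between repeated simulations.
* The Metropolis-within-Gibbs sampler is tuned for cohorts of up to
  a few hundred clones; much larger cohorts would warrant a
  gradient-based sampler.
* Onset back-extrapolation trusts the fitted late-life rate; for
  clones that decelerated, it reports when a clone growing at the
  *observed* rate would have been founded, which is exactly the
  discrepancy the historical-growth and phylodynamic comparisons
  are designed to expose.
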