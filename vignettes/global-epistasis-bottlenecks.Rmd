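---
title: "Functional bottlenecks from global epistasis: model, calibration and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional bottlenecks from global epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Combinatorial fitness landscapes between two protein variants with distinct,
mutually exclusive functions (for example a red- and a blue-fluorescent
variant separated by a handful of substitutions) sometimes show a *functional
bottleneck*: among all mutational paths connecting the two variants, every
path that keeps the protein functional passes through a single "jumper"
genotype where the phenotype switches. Bottlenecks are often attributed to
*network epistasis* — irreducible pairwise and higher-order interactions
between residues. `episcape` implements a deliberately minimal
counter-model: a landscape with **global epistasis only**, in which fitness
is a nonlinear function of a perfectly additive underlying trait, and asks
whether bottlenecks emerge anyway. They do, with probability close to one,
once the model is calibrated — which is the point of the package.

## The model

A genotype is a binary vector $a \in \{0,1\}^L$ over $L$ sites. Each site
carries a random single-mutation effect (SME) $h_i$, drawn i.i.d. from a
symmetric a-priori distribution $P(h)$ and then shifted once so that
$\sum_i h_i = 0$. The underlying trait is additive,
$$E(a) = \sum_{i=1}^L h_i a_i,$$
and two sigmoidal fitness functions, mirror images of each other, define the
two phenotypes:
$$F_B(E) = \frac{\phi_0}{1 + e^{\beta(E_{th} - E)}}, \qquad
  F_R(E) = \frac{\phi_0}{1 + e^{\beta(E_{th} + E)}}.$$
In the sharp-threshold regime $\beta \gg 1$ used throughout, a genotype is
functional blue iff $E > E_{th}$, functional red iff $E < -E_{th}$, and
nonfunctional otherwise. All path-space analyses in the package work
directly on the trait in this limit; the smooth fitness functions are used
only where a finite $\beta$ matters (the synthetic fixture generator).
Boundary values $E = \pm E_{th}$ are classified nonfunctional (strict
inequalities), consistent with the strict path-viability condition below.

Two SME distributions are built in:

* **gaussian** — unit variance by default. The scale of $P(h)$ can be
  absorbed into $E_{th}$ and $\beta$, so fixing it loses no generality;
  `sigma` is exposed for completeness.
* **pareto_cutoff** — flat below a shoulder `xm`, a power-law tail
  $\propto |h|^{-(\alpha+1)}$ above it, and a hard cutoff beyond which the
  density vanishes. Defaults `alpha = 0.7`, `xm = 0.1`, `cutoff = 2` mirror
  the fat-tailed SME spectra seen in measured fluorescent-protein
  landscapes. The normalization constant has a closed form, and sampling is
  by inverse CDF on the piecewise density — exact, fast, and deterministic
  under seeding — rather than by rejection.

## Reference variants: the tuning procedure

The two reference variants are built from the all-zero ancestor by
accumulating mutations one at a time. With probability $p$ a *greedy* step
picks the unoccupied site with maximum impact towards the target (largest
$h_i$ for blue, most negative for red; ties — a zero-probability event for
continuous $P(h)$ — go to the lowest index for determinism). With
probability $1-p$ a *random* step mutates a uniformly chosen unoccupied
site, which may well oppose the target. Tuning stops the first time the
trait crosses the target: $E > E_T$ (blue) or $E < -E_T$ (red). The two
colors are tuned independently, on independent RNG substreams derived from
the instance seed, so each trace is individually reproducible. If all $L$
sites are exhausted without crossing, the package raises an explicit
tuning-failure condition rather than silently retrying; ensemble drivers
resample a fresh substream and count the failures.

The $M$ sites where the two tuned genotypes differ define the instance's
combinatorial landscape. The "selected SMEs" reported per instance are the
$h_i$ at those $M$ differing sites; the effects at each reference's own
mutated sites (which additionally include sites mutated in *both*
references) are exposed separately as `smes_by_reference`, since both
accountings are defensible and the difference matters only for the rare
shared sites.

## Path space: EC, jumpers, path counts

Between the two references lie $2^M$ intermediates, reached by introducing
the $M$ differing mutations in any order: $M!$ *directed* paths (each
mutation introduced exactly once, no back-mutations). A path is viable at
threshold $E_{th}$ if all of its $M-1$ intermediates satisfy
$|E| > E_{th}$; endpoints are always retained. The connectivity threshold
$E_C$ is the largest threshold at which at least one path survives — a
maximin (widest-path) problem:
$$E_C = \min\Big(\max_{\text{paths}} \min_{\text{intermediates}} |E|,\;
                 E_{min}^{ref}\Big),
  \qquad E_{min}^{ref} = \min(E_B^{ref}, |E_R^{ref}|).$$
The cap exists because raising the threshold beyond the weaker reference
would disconnect the endpoints themselves; when the cap is active the
instance is reported with topology `capped_no_jumper`.

$E_C$ is computed by dynamic programming over the subset lattice in layer
order, $O(M 2^M)$, never by enumerating $M!$ orders; a factorial
brute-force enumeration serves as the test-suite oracle at $M \le 6$.
Surviving-path counts use the analogous path-count DP with the *closed*
condition $|E| \ge E_C$, so the jumper itself is part of the surviving
graph (the strict/closed distinction exactly at $E_C$ is a measure-zero
choice for continuous $P(h)$; the closed convention keeps the jumper in
the exported graph, matching how such graphs are usually drawn). Counts are
kept in doubles, which are exact here: $14! \approx 8.7\times10^{10} <
2^{53}$.

Jumpers are intermediates with $|E| = E_C$ (relative tolerance $10^{-12}$;
exact ties between distinct states are all reported) lying on at least one
surviving path, determined via forward and backward path-count DPs. The
jumper position $j$ is its mutational distance from the blue reference (the
minimum layer if several). The topology class records whether the jumper
connects by single mutations to one or to several surviving states of the
opposite phenotype sign. The numerical proxy used during calibration calls
an instance "single-jumper" when $E_C < 0.9\,E_{min}^{ref}$ (strict).

Instances with $M > 14$ are excluded from path analysis (the default
`max_M_paths = 14` keeps subcube enumeration at $\le 16384$ states);
instances with $M = 1$, which the tuning procedure essentially never
produces, would also be excluded since they have no intermediates.

## Calibration

The calibration pipeline fixes $(L, p, E_T)$ so the model reproduces the
phenomenology of measured bottlenecked landscapes:

1. `L = 500`, a typical protein length; results depend on it weakly.
2. For each $p$ on a grid (default $0.05, 0.10, \dots, 0.60$),
   `calibrate_ET_for_p()` finds $E_T(p)$ such that the mean mutation count
   is $\langle M\rangle \approx 8$ — large enough to be interesting, small
   enough that $2^M$ enumeration is cheap. The search is a bisection with
   common random numbers (the same instance seeds across all $E_T$
   evaluations), which makes $\langle M\rangle(E_T)$ effectively monotone
   and the search deterministic; the stopping tolerance is
   $|\langle M\rangle - 8| < 0.25$.
3. $E_T(p)$ is approximately linear; `fit_ET_line()` fits it by OLS.
4. `scan_p()` re-generates ensembles along the grid at line-evaluated
   $E_T$ and records the overshoot $\langle E_B^{ref}/E_T\rangle$, the
   bottleneck strength $\langle E_C/E_{max}^{ref}\rangle$ (restricted to
   single-jumper-proxy instances with $M \le 14$), and the single-jumper
   probability.
5. `select_p()` picks the smallest grid $p$ whose single-jumper
   probability reaches `prob_threshold = 0.99` — our operationalization of
   "very close to one", which the source phenomenology leaves qualitative.

Two boundary behaviors are worth knowing. At very small $p$ the mean-$M$
constraint can be *infeasible*: even as $E_T \to 0^+$ a tuning trace still
needs several steps, because the number of steps is
$\min(\mathrm{Geom}(p), T)$ with $T$ the first-passage time of a symmetric
random walk above zero, whose tail decays only as $n^{-1/2}$. At
$p = 0.05$ this floor already exceeds a mean $M$ of 8. Such grid points are
recorded as `NA`, excluded from the line fit, and still scanned (at the
line's $E_T$, when positive) so the probability curves cover the grid.
Second, the mean-$M$ floor at larger $p$ (e.g. $\approx 2$ at $p \to 1$)
is what makes the target reachable everywhere else.

With the defaults the pipeline lands on $p = 0.30$ at threshold 0.99 for
both distributions (the single-jumper probability at $p = 0.25$ hovers
around 0.96–0.98), with calibrated $E_T$ close to 2.0 (Gaussian) and 1.1
(Pareto cutoff) near $p = 0.25$–0.26. The two named presets
`gaussian_calibrated` ($p = 0.26$, $E_T = 2.0$) and `pareto_calibrated`
($p = 0.25$, $E_T = 1.1$) pin the operating points used for all reported
ensemble statistics.

## What the calibrated ensembles show

At the calibrated operating points (2000-instance desk-scale ensembles;
20000 at "paper scale" via `n_instances`):

* $\langle M\rangle \approx 8$ with a broad distribution reaching beyond
  16, and $M \ge 2$ always — a single mutation cannot bridge the $2 E_T$
  gap between the two functional regions at these parameters.
* The blue reference overshoots its target moderately,
  $E_B^{ref}/E_T \approx 1.5$ on average: tuning typically ends on a greedy
  step, which for $L = 500$ adds close to the pool maximum.
* The greedy-step count per trace has mode 1: one large selected effect
  plus a few near-neutral random ones. The selected-SME distribution is
  correspondingly strongly bimodal — the balance of nearly neutral and
  strongly non-neutral effects that creates sharp functional transitions.
* $E_C < E_{min}^{ref}$ with probability $\ge 0.99$: a genuine bottleneck,
  not the trivial cap.
* The jumper sits mid-path ($j/M$ peaked at $1/2$), and the surviving-path
  count at $E_C$ grows roughly exponentially with $M$.
* The ratio $E_C/E_{max}^{ref}$ is approximately independent of $M$ and
  concentrates around $0.4$–$0.5$ (mean $\approx 0.38$, mode
  $\approx 0.40$, upper edge near $0.5$). A simple argument bounds it by
  $1/2$: the jump mutation must carry the trait from $+E_C$ to $-E_C$, so
  $2E_C \lesssim \max_i |\tilde h_i| \approx E_{max}^{ref}$. The bound is
  approached but not attained on average, because the small random-step
  effects available before the jump cannot position the path exactly at
  $+E_C$.

## The measured-landscape analyzer

`read_landscape_table()` ingests a complete $2^K$ genotype table
(`genotype,F_blue,F_red`, TSV or CSV) and validates completeness,
uniqueness and non-negativity, naming offending rows. The pipeline then
mirrors the standard deconvolution analysis of two-phenotype combinatorial
data: normalize each fitness to its own reference
(`normalize_fitness()`), invert the global nonlinearity with the power law
$\phi^{-1}(x) = x^{0.44}$ (`deconvolve_trait()`; the exponent is a
configurable default — inferring the nonlinearity from data is out of
scope and methodologically contested), combine the two exclusive
phenotypes into the signed trait $E = E_B - E_R$, and analyze:

* `sme_spectrum()` — all $K 2^K$ single-mutation effects
  $\Delta E_i(a)$; for an additive landscape they are
  background-independent, so their spread over backgrounds measures
  network epistasis.
* `fit_pareto_tail()` — truncated-tail MLE of the Pareto exponent for
  magnitudes above `xm` (conditional on exceedance, optional hard cutoff),
  with the standard error from observed information. The choice of MLE
  with fixed `xm` is ours; sensitivity to `xm` should be checked over a
  small grid. Without a cutoff the estimator reduces to Hill's.
* `empirical_bottleneck()` — the full path-space analysis on the measured
  hypercube, treating the all-zeros corner as the blue reference.

Because the experimental dataset this emulates cannot be bundled,
`make_fixture()` generates synthetic tables with the same structure: a
calibrated-model instance with exactly $M = K$ differing sites, mapped
through the two-color sigmoid at a finite sharpness (default
$\beta = 10$, so the map is smooth and invertible in practice) and
multiplied by lognormal measurement noise of chosen coefficient of
variation (multiplicative noise keeps fitness non-negative, as
fluorescence-style measurements do). With `noise_cv = 0` the deconvolution
recovers the generating trait ordering exactly — any monotone
deconvolution exponent gives rank correlation 1 — which is the round-trip
the tests assert. The fixture is synthetic and labelled as such; analyzing
a real table is supported through the same reader but never required.

## What the synthetic tests do and do not show

The generator emulates: exclusive two-phenotype structure, fat-tailed or
Gaussian SME spectra, reference-normalized fitness, multiplicative noise.
It does not emulate: network epistasis (absent by construction — that is
the model's point), measurement floors/saturation, missing genotypes,
promiscuous intermediates, or insertions. A passing suite therefore shows
the pipeline is correct and the global-epistasis null reproduces
bottleneck topology; it does not show that any particular real landscape
lacks network epistasis.

## Numerical choices, in one place

* Zero-sum shift applied once after sampling; never re-applied on subsets.
* Greedy ties: lowest site index. Jumper equality tolerance: relative
  $10^{-12}$. Proxy and phenotype boundaries: strict inequalities.
* Bisection: bracket by doubling from $E_T = 0.5$ (cap 64), tolerance
  0.25 on mean $M$, common random numbers across evaluations.
* Ensemble sizes: 2000 by default (calibration `n_per_point` likewise);
  the acceptance script uses 2000 throughout, and the test suite 1000 per
  calibration point. Standard errors accompany every reported mean.
* Seeding: one master seed; substreams via
  `substream_seed(seed, counter)` (MINSTD step, exact in doubles);
  instance-internal streams use fixed counters (1 pool, 2 pair, then
  blue/red inside the pair). Aggregation is order-independent.

## Known limitations

* Directed paths only; allowing back-mutations (pure connectivity) could
  only raise $E_C$ and is not implemented.
* $M > 14$ instances are excluded from path statistics, as in the source
  phenomenology; an analytic treatment would remove the restriction but is
  out of scope.
* No population-genetic dynamics: the tuning procedure is a caricature of
  directed evolution, not a fixation process.
* The deconvolution exponent is fixed, not inferred; only
  reference-normalized fitness conventions are supported.
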