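---
title: "Choosing a coarse-grained representation by model evidence"
author: "nsrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a coarse-grained representation by model evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsrep)
```

## The problem

Integrative structural modeling determines the architecture of a
macromolecular assembly by sampling configurations of a simplified
("coarse-grained") model against experimental restraints — here, chemical
crosslinks, which report that two residues were within a crosslinker's span.
Before any production sampling can start, the modeler must choose a
*representation*: how many contiguous residues each spherical bead absorbs,
and which chains move as rigid bodies. That choice trades accuracy against
cost. Fine beads can fit the data closely but inflate the parameter space
and the per-step cost of sampling; coarse beads are cheap but may wash out
the signal. In practice the choice is usually made by convention.

`nsrep` makes the choice quantitative. For each candidate resolution it
estimates the **Bayesian model evidence**

$$Z_R \;=\; P(D \mid R) \;=\; \int L(\theta)\,\pi(\theta)\,d\theta,$$

the likelihood of the crosslink data $D$ averaged over the prior of the
representation's parameter space $\theta$ (the bead coordinates). Under
equal prior odds for two representations, the ratio $K = Z_{R_1}/Z_{R_2}$
(the Bayes factor) says which representation the data prefer. Because the
evidence averages rather than maximizes, it penalizes needlessly fine
representations automatically: enlarging the parameter space without a
matching gain in likelihood dilutes $Z$.

A representation is then called *optimal* when it combines high evidence
with low sampling cost per Monte Carlo step — both criteria, not either
alone.

## Evidence by nested sampling

The integral above is intractable in the dozens-to-thousands of dimensions a
bead model has, so it is computed by nested sampling. Let the *prior mass*

$$X(\lambda) = \int_{L(\theta) > \lambda} \pi(\theta)\, d\theta$$

be the fraction of prior with likelihood above a threshold. Then
$Z = \int_0^1 L(X)\,dX$ — a one-dimensional integral over a monotone curve.
Nested sampling tracks it with a population of `n_live` prior draws ("live
points"):

1. draw `n_live` models from the prior and compute their likelihoods;
2. remove the worst one (likelihood $L_i$), recording it as a "dead point"
   at the deterministic shrinkage estimate $X_i = e^{-i/n_\mathrm{live}}$;
3. replace it with a fresh prior draw *constrained* to beat $L_i$
   (draws are rejected until one does);
4. repeat, accumulating $Z \approx \sum_i L_i\,(X_{i-1} - X_i)$.

`integrate_evidence()` adds a remainder term, the mean live likelihood times
the final prior mass, so the quadrature weights sum to exactly one; a
constant likelihood then integrates to itself to machine precision, which is
the package's most basic self-test. All arithmetic is in log space through a
log-sum-exp primitive.

### Termination

Runs stop on whichever of three conditions triggers first:

* **failure counter** — the constrained sampler failed `max_attempts` draws
  in a row, `max_consecutive_failures` times in a row: the likelihood
  surface above the current threshold has become too thin to hit by fresh
  prior draws;
* **plateau counter** — `max_plateau_hits` consecutive iterations produced
  samples on a likelihood plateau, detected by
  $L_\mathrm{new}/L_\mathrm{worst} < X_i/X_{i+1}$ (strict, in log space):
  likelihood is growing slower than prior mass is shrinking, so further
  iterations cannot add evidence;
* **iteration cap** — `max_iterations`, set high; it exists so a
  misconfigured run cannot spin forever.

The plateau test is applied to the last candidate generated in an iteration
whether or not it was accepted, and the plateau counter is checked before
the failure counter. This matters for the degenerate but diagnostic case of
an exactly flat likelihood: every constrained draw fails (strict
inequality), yet every draw also sits on the plateau, and the run correctly
reports plateau termination with $\log Z = \log L_0$.

### Posterior repartitioning

Nested sampling is inaccurate when the prior is very unlike the posterior —
precisely the situation in integrative modeling, where the stereochemistry
prior is nearly flat and the crosslink likelihood is concentrated. The
package therefore *repartitions* the posterior: a random subset of the
crosslinks (`prior_fraction`, default 30%) is moved into a **modified
prior** alongside the stereochemistry terms, and only the remaining
crosslinks form the likelihood. The product — the posterior — is unchanged,
which `score_model()` preserves identically and the test suite checks over
thousands of random splits. The modified prior is sampled by Metropolis
Monte Carlo, so its normalization constant never enters within a
representation. Comparing evidences *across* representations therefore
assumes comparable prior normalization across parameter spaces of different
dimension; this is an assumption of the method as implemented, stated here
rather than hidden.

Because the prior subset is random, the package can rerun the whole
pipeline under independent splits (`prior_robustness()`) and report the
Spearman rank correlation of the candidate orderings — a direct check of
how much the arbitrary split influenced the conclusion. The output is
descriptive; no pass/fail threshold is imposed.

## The scoring system

Beads are spheres of volume-equivalent radius
$r(n) = (3 n V_\mathrm{res} / 4\pi)^{1/3}$ with
$V_\mathrm{res} = 130\,\mathring{A}^3$, the mean amino-acid volume. Three
restraint families enter:

* **excluded volume** — $-\tfrac{k_\mathrm{ev}}{2}\sum_{i<j}
  \max(0,\, r_i + r_j - d_{ij})^2$ over bead pairs, pairs within one rigid
  body exempt;
* **chain connectivity** — the same one-sided harmonic on
  $d_{ij} - (r_i + r_j)$ for beads consecutive along a chain: bonded beads
  may touch or overlap freely but pay for gaps;
* **crosslinks** — per link,
  $\log\!\left[\omega + (1-\omega)\big/\big(1 + e^{(d - d_0)/\lambda}\big)\right]$
  on the center-to-center distance $d$ of the beads holding the two
  residues: a sigmoid that is $\approx 1$ for satisfied links and decays to
  the false-positive floor $\omega$ beyond the cutoff.

Distances are center-to-center; bead radii enter only the stereochemistry
terms. The floor $\omega$ keeps every log-likelihood term in
$(\log\omega, 0)$, which bounds $\log Z$ and is what makes plateau detection
well defined.

Defaults, with units and reasons:

| parameter | default | unit | role |
|---|---|---|---|
| `d0` | 21 | Å | sigmoid midpoint; center-to-center analogue of a lysine-reactive crosslinker span |
| `slope` | 2 | Å | sigmoid width; sharper values approximate a hard cutoff |
| `omega` | 0.01 | — | false-positive floor; bounds the likelihood from below |
| `k_ev`, `k_conn` | 1 | Å⁻² | stereochemistry force constants; 0 disables a term (used by analytic toys) |
| `prior_fraction` | 0.3 | — | crosslink share moved into the modified prior |
| `n_live` | 50 | — | live points; should be at least `count_free_parameters()` of the candidate |
| `n_steps_per_sample` | 50 | — | Metropolis steps per prior draw |
| `bead_step`, `rb_trans_step` | 3 | Å | proposal scales |
| `rb_rot_step` | 0.3 | rad | rigid-body rotation scale |

The number of free parameters of a candidate is $3n + 6m$ for $n$ flexible
beads and $m$ rigid bodies, available as `count_free_parameters()`; the
live-point guidance above follows from it.

## Sampling the modified prior

Each prior draw is a fresh bond-respecting random initialization followed by
`n_steps_per_sample` single-temperature Metropolis steps (one flexible bead
translated, or one rigid body translated and rotated about its centroid;
proposals symmetric). Fresh draws rather than evolved live points keep the
draws independent by construction, at the price of needing enough Metropolis
steps per draw to forget the initialization — the test suite checks the
induced bond-length distribution of a two-bead system against its exact
radial density on a dense grid. The hot loop is a compiled kernel that
re-scores the full restraint set at every step, driven by R's RNG so every
run is reproducible from its seed; a pure-R reference implementation of the
same kernel is cross-checked in the tests. A replica-exchange ladder could
be layered over `sample_from_modified_prior()` without touching the
nested-sampling loop; at the problem scales targeted here, single-temperature
chains sample the (mild) modified prior adequately.

Initial bead placement uses a bounding sphere of three times the
volume-equivalent radius of the whole assembly. An alternative sizing — a
multiple of the *sum* of bead radii — grows linearly with bead count and
strands fine-grained starting models so far apart that every crosslink sits
at its probability floor, where nested sampling terminates on the resulting
plateau; scaling with assembly volume keeps starting densities comparable
across candidate representations of the same assembly.

## Collation and the selection rule

Per candidate, `n_runs` independent runs (distinct derived seeds; optionally
parallel, with results independent of the worker count) yield the mean
log-evidence, its standard error across runs, and the mean **sampling time
per Metropolis step** — measured inside the kernel only, so nested-sampling
bookkeeping does not contaminate the efficiency comparison. Runs that fail
outright are relaunched with fresh seeds up to a retry cap.

Selection applies two criteria in a fixed order:

1. **efficiency filter** — keep candidates whose per-step time is within
   `time_fold` (default 3) of the fastest;
2. **evidence overlap** — among those, find the highest mean evidence and
   call optimal every candidate whose `mean ± 1 SEM` interval overlaps the
   best one's.

A candidate with the best evidence overall can therefore be excluded purely
for being slow — deliberately so, since the point of coarse-graining is
affordable sampling. The SEM multiplier is configurable; 1 SEM is the
default because the interval is meant as "statistically indistinguishable
given run-to-run scatter", not as a confidence interval with coverage
guarantees. Only evidence *differences* matter: shifting every candidate's
log-evidence by a constant provably leaves the report unchanged.

## What the synthetic generator emulates — and what it does not

Real benchmark systems would require external structures, so the package
generates its own ground truth: each chain is a fixed-bond (3.8 Å) random
walk with soft self-avoidance, confined so the assembly's radius of gyration
is about $3\,N^{1/3}$ Å — the scaling of a compact globule. Crosslinks are
simulated from the true structure: with probability $1 - \mathrm{fp}$ a
uniformly chosen residue pair within the cutoff (default 25 Å), otherwise a
uniformly chosen random pair; duplicates are allowed, as in real data.

This captures the statistical structure the method consumes — compact
multi-chain geometry, distance-censored pair observations, a false-positive
fraction — and nothing else. It does not emulate sequence-dependent packing,
crosslinker chemistry or reactivity bias, under-crosslinked surfaces, or
experimental error in residue assignment. Passing tests therefore
demonstrate that the estimator and the selection rule behave correctly on
data with the assumed statistics, not that any particular real assembly
would yield the same optimal resolution.

## Numerical choices

* Shrinkage is deterministic, $X_i = e^{-i/n_\mathrm{live}}$; sampling the
  widths instead is a known variant, not implemented.
* Worst-point ties break by live-point index, so runs are exactly
  reproducible.
* Quadrature is the rectangle rule plus the live-point remainder; the
  remainder is required for the constant-likelihood identity to hold
  exactly.
* The plateau inequality is strict; a likelihood increment exactly equal to
  the shrinkage rate does not count as a plateau.
* Degenerate inputs: an empty crosslink table repartitions to two empty
  sets with a warning, and the likelihood is then identically zero, so
  $\log Z = 0$ exactly; a single-run candidate reports SEM 0 with an
  explicit warning; a run whose scorer cannot produce even one initial live
  point raises a classed run-failure error that the orchestrator converts
  into a relaunch.

## Problem sizes used in tests and the acceptance script

The bundled analyses run at desk scale, chosen to finish in minutes on one
core while keeping the candidates materially different: a four-chain,
600-residue synthetic assembly with 60 crosslinks; candidate resolutions
{1, 5, 20, 50} residues per bead (600 down to 12 beads); 3 runs of 25 live
points, 30 Metropolis steps per draw, iteration cap 120; robustness over 3
random repartitions of candidates {5, 20, 50}. Analytic checks use a 1-D
toy (uniform prior on [0, 10], Gaussian log-likelihood) whose evidence is
known by quadrature, and a two-bead system integrable on a dense grid.
These sizes are scaled-down analogues of production settings (50 live
points, 50 steps per draw, 5 runs — the package defaults), not
recommendations for real assemblies.

## Known limitations

* Evidence comparisons across representations inherit the prior
  normalization assumption described above.
* Fresh-draw constrained sampling becomes expensive when the constrained
  prior mass is tiny; the failure counter converts that regime into
  termination rather than stalling, at the cost of truncating the evidence
  accumulation (the remainder term absorbs most of what is lost).
* Single-temperature Metropolis limits how rugged a modified prior the
  sampler can traverse; heavily restrained prior sets may need more steps
  per draw than the default.
* Candidates whose representations differ only in a small region produce
  evidence differences smaller than run-to-run scatter; the SEM-overlap
  rule then correctly reports them as indistinguishable rather than
  inventing an ordering.
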