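---
title: "Methods: reproductive value, fitness and selection identities under stochastic demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproductive value, fitness and selection identities under stochastic demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvprice)
```

## The model and its assumptions

`rvprice` works with finite instantiations of a class-structured population
model with fluctuating demography. A model instance consists of:

* a finite **class set** with a ploidy $L_x \ge 1$ per class (so haploidy,
  diploidy and haplodiploidy coexist in one framework);
* a finite, row-stochastic **Markov environment chain** $\Pi$;
* a finite **genotype space** with per-locus allele dosages — within each
  locus the dosages of a genotype sum to one, so a diploid heterozygote
  carries dosage $1/2$ of each allele;
* a finite **phenotype set** with a designated background phenotype $a_0$;
* a stochastic **reproduction kernel** with finite outcome support, giving
  each parent's array of offspring-equivalents per parental haploid set,
  $w^i_{x',g'}$; and
* a per-individual **mutation kernel**, applied after reproduction.

The theory rests on four structural assumptions, all of which
`validate_model()` checks mechanically rather than trusting the kernel
author: permutation equivariance (the listing order of individuals carries no
information), genotype-through-phenotype (genotypes influence offspring
*numbers and classes* only via phenotypes; they do of course determine
offspring genotypes), uniform boundedness of shares, and no route to
extinction. A fifth, implicit requirement is that the ploidy-weighted column
sums $\sum_i L_i w^i_{x',g'}$ are whole numbers in every outcome — next
year's population must consist of whole individuals — and the enumeration
layer enforces it at every transition.

Share accounting is per haploid set and depends on the coreplicon: a parent
contributing one gamete scores $1/(L_{x'} L_{\text{parent}})$ and a surviving
self scores $1/L_{\text{parent}}$. These computations (`gamete_share`,
`family_shares`) run in exact rational arithmetic — a small built-in rational
class with integer-valued numerators and denominators — because the point of
that module is exactness, not approximation. A reproduction model fixes one
coreplicon; cross-coreplicon conflict is out of scope, and `family_spec`
carries per-coreplicon ploidies only so that the share tables of the same
family can be compared across coreplicons (ploidy 0 marks absence, e.g. a
mother at the Y, and such parents simply have all shares zero).

## Reproductive value

Under the background phenotype the class dynamics decouple from the
genotypes, and the demographic process is an exact finite Markov chain on
(environment, class tally) states. Candidate reproductive-value functions are
keyed by that tally — not by ordered class arrays — which builds the
permutation clause into the data structure. The transition operator $T$ maps
a candidate descendant assignment to the implied parental one by exhaustive
enumeration of kernel outcomes and next environments.

`solve_rv()` finds the fixed point two independent ways and cross-checks
them:

* **power iteration** from the uniform candidate, exploiting that the
  candidate set is $T$-invariant, stopping at sup-norm change below `tol`
  (default $10^{-12}$), erroring after `max_iter` (default $10^4$);
* a **direct linear solve** of the stacked system $(T - I)\phi = 0$ plus one
  ploidy-weighted sum-to-one constraint per state, by QR least squares.

Existence and uniqueness are not guaranteed at this level of generality, so
the solver also re-runs power iteration from `probe_starts` random
candidates and warns if distinct fixed points appear; every fixture ships
with a unique one. Requests for reproductive value at states unreachable
under the neutral process are errors, not extrapolations.

## The Taylor year and fitness

The selective year draws its initial state from the ergodic distribution of
the full (genotype-inclusive) neutral chain — mutation is what keeps that
chain irreducible — and applies an arbitrary map from (class, genotype) to
phenotype for exactly one year. Fitness is Williams' reproductive value
relative to the class expectation, $(W_i - \phi_i)/\phi_i$.

Two numerical conventions matter here:

* **Numerator form.** Every population mean or covariance involving fitness
  is accumulated as $\phi_i \mathcal{F}_i = W_i - \phi_i$, which is finite
  even when $\phi_i = 0$ and an individual's fitness is flagged infinite.
  The ratio-form fitness is display output; the identities are computed in
  numerator form throughout.
* **The $0/0$ case.** When $\phi_i = 0$ and $W_i = 0$ the ratio is genuinely
  undefined; `fitness()` returns 0 with a flag so users can audit the
  convention.

Realized and expected fitness are both exposed because the identities use
both: the reproductive-value-weighted mean of *realized* fitness is zero in
every single realization (a bookkeeping identity of the sum-to-one
constraint), while *expected* fitness is what enters the Price covariance.

## Verification strategy

Every identity is checked by exhaustive enumeration where the state space
permits, with tolerance $10^{-10}$; the solver tolerance is $10^{-12}$.
The default fixtures use dyadic kernel probabilities wherever possible, so
most residuals sit at the $10^{-16}$ level. Monte Carlo modes exist for
instances too large to enumerate: one-year checks sample (outcome, next
environment) pairs from the exact support, and the martingale check simulates
whole histories stepwise; both report estimate, standard error and a
$\pm 3$ SE interval. A subtlety of the martingale check is that it can be
*degenerate*: whenever one ancestor class owns the entire gene pool, or a
fixture conserves class totals realization-wise (the haplodiploid fixture
does, for the same reason maternal and paternal X-pools are fixed fractions),
the tracked quantity is constant along every path and only rounding noise
remains. The Monte Carlo mode detects a path variance below $10^{-10}$ and
reports the residual as exactly zero rather than dividing noise by noise; the
age-structured fixture from a mixed-age state provides the non-degenerate
test case.

Breeding values are reproductive-value-weighted least squares of expected
fitness on allele dosages, solved by SVD with minimum-norm resolution of
rank-deficient designs — the fitted p-score $\beta$ is unique even when the
allelic weights are not. Because every locus's dosages sum to one, constants
lie in the design span, so the normal equations *deliver* the centring
property $\operatorname{ave}_\phi \beta = \operatorname{ave}_\phi(\text{target})$
rather than having it imposed; the tests check this. Ensemble breeding values
minimize the ergodic-distribution-weighted criterion by stacking states.

One design constraint ties the Taylor year to the neutral process:
reproductive value is defined only on states reachable under neutrality, so
fixtures are built with selective maps that shift outcome *probabilities*
without enlarging the demographic *support*. A user-supplied kernel whose
selective year reaches new class tallies will get a clear error from the
reproductive-value lookup rather than silently extrapolated values.

## The fixtures: what they emulate and what they do not

The fixtures are first-class models chosen so that full enumeration of every
theorem stays comfortably below $10^5$ (state $\times$ outcome $\times$
environment) terms — at most six individuals, three classes, two
environments, a handful of genotypes:

* `make_clonal(N)` — degenerate exact-survival model; closed forms
  ($\phi^* \equiv 1/N$, zero fitness everywhere) anchor the solver tests.
* `make_haplodiploid()` — the workhorse: diploid females, haploid males, one
  biallelic locus with Mendelian segregation, environment-dependent family
  sizes, a class tally fluctuating between one and two females, recurrent
  mutation at $1/16$ per allele. Kernel probabilities are dyadic by default;
  the selective map gives homozygous-*a* females a fecundity and
  mother-choice advantage.
* `make_age_density()` — two haploid age classes with survival implemented
  as a self-offspring into the next age class, environment-dependent
  fecundity and density-dependent adult survival; its class distribution
  fluctuates and its martingale is non-degenerate from mixed-age states.
* `make_bethedge()` — a constant-size haploid population competing for
  slots, with a risky phenotype scoring 2 in the good environment and
  $1/2$ in the bad one. It exhibits the characteristic bet-hedging pattern:
  conditional selection on the risky type flips sign with the environment,
  while the ensemble Price equation weighs the two through the arithmetic
  expectation of fitness.

Mutation rates ($1/16$ per allele for the haplodiploid fixture, $1/8$ for
the clonally transmitting ones) are chosen high enough that the
genotype-inclusive chain mixes quickly and its exact stationary distribution
has full support on a few dozen states; they are maintenance parameters of
the neutral process, not biologically calibrated quantities.

What passing these suites shows is that the *identities* — which are exact
theorems — hold in an implementation that makes all of their ingredients
explicit. What it does not show is anything statistical about real
populations: real class spaces are large or continuous, real kernels have
unbounded support, real environments are not stationary Markov chains, and
reproductive value would have to be estimated rather than solved. The
fixtures also exercise no social interactions (the kernel format permits
class- and phenotype-dependent interactions, but no fixture uses them) and
a single coreplicon per model.

## Numerical and design choices

* Probabilities are doubles; shares in the family-accounting module are
  exact rationals. Dyadic fixture probabilities make most checks exact in
  floating point too.
* `extract` orders individuals canonically (class, then genotype); the
  permutation assumption makes any order equivalent, and determinism aids
  testing and reproducibility.
* Stationary distributions are found by direct linear solve below 2000
  states and power iteration above, to residual $10^{-12}$; chains with
  multiple recurrent classes or a periodic recurrent class are rejected with
  diagnostics, since the theory presumes ergodicity.
* Simulation derives per-year RNG substreams from the root seed, so
  trajectories are reproducible and extendable.
* Model files carry kernels either as named builtins with parameters or as
  explicit outcome tables (clonal transmission); arbitrary Mendelian kernels
  are R functions and cannot round-trip through a table, which is why the
  builtin dialect exists. Rational strings like `"1/4"` in files are
  preserved verbatim on a round trip.
* Problem sizes: the demographic chains here have 2–5 states, the
  genotype-inclusive chains up to 36, and the full ensemble verifications
  enumerate a few thousand terms; the whole test suite runs in well under a
  minute per module.

## Known limitations

Only finite class, environment and genotype spaces are supported; the
continuous-class generality of the underlying theory is out of scope.
Transmission is fair in expectation — meiotic drive and the transmission-bias
term of the Price equation are excluded by assumption. Selection is studied
over a single year (knock-on effects appear only through gene frequencies),
mutation is excluded from $\Delta^*$ by construction, and interactions
between relatives are not modelled. Non-uniqueness of the fixed point is
detected and reported, not resolved.
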