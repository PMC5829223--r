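# rvprice

Natural selection in a finite, class-structured population rarely happens
against a fixed demographic backdrop: the environment fluctuates, the numbers
in each class (sexes, ages, conditions) fluctuate with it, and different
classes may even carry different ploidies — haploid males beside diploid
females, X-linked loci beside autosomes. `rvprice` is a toolkit for studying
how Fisher's apparatus of reproductive value, individual fitness, the Price
equation and the fundamental theorem of natural selection behaves in exactly
that setting, on fully enumerable model instances where every identity of the
theory can be checked to machine precision.

It is aimed at theoreticians in evolutionary biology and population genetics
who want executable, verifiable versions of these constructions — either to
explore small models or to test conjectured extensions against exact
enumeration.

## The model in brief

A model instance specifies a finite class set with per-class ploidies
$L_x$, a finite Markov environment chain $\Pi$, a finite genotype space with
per-locus allele dosages, and a stochastic **reproduction kernel** with finite
outcome support: for environment $e$ and population arrays
$(\mathbf{x}, \mathbf{g}, \mathbf{a})$ it returns each individual's array
$w^i_{x',g'}$ of offspring-equivalents *per parental haploid set*. A diploid
parent contributing one gamete to a diploid offspring scores $1/4$; survival
counts as a self-offspring worth $1/L$. All loci live on one coreplicon, so
these share rules are exact rational arithmetic (`gamete_share`,
`family_shares`).

Under a uniform background phenotype the process is *neutral*; its ergodic
distribution $\mathcal{D}(a_0)$ and the **transition operator**

$$(Tf)(x, e, \mathbf{x}) = \mathbb{E}_{e'}\mathbb{E}_{\mathbf{x}'}\Big[\sum_{y'} f(y', e', \mathbf{x}')\, L_{y'}\, u^{x}_{y'}\Big]$$

define **reproductive value** $\phi^*$ as the fixed point of $T$ in the set of
candidates that are nonnegative, vanish on empty classes and have
ploidy-weighted population sum one. In one selective ("Taylor") year, drawn
from $\mathcal{D}(a_0)$, an arbitrary class-and-genotype-to-phenotype map is
switched on, and each individual's fitness is

$$\mathcal{F}_i = \frac{W_i - \phi_i}{\phi_i}, \qquad
W_i = L_i \sum_{y'} \phi(y', e', \mathbf{x}')\, w^i_{y',+},$$

Williams' reproductive value relative to the class expectation. The package
then verifies, by exhaustive enumeration or Monte Carlo:

- the **martingale property** of lineage reproductive value in the neutral
  process;
- the **Price equation**
  $\mathbb{E}[\Delta^* \operatorname{ave}_\phi p \mid e,\mathbf{x},\mathbf{g}]
   = \operatorname{cov}_\phi(p, \mathbb{E}[\mathcal{F}])$ for any p-score $p$,
  conditionally and over the ensemble;
- the **fundamental theorem**: with breeding values of expected fitness as
  the p-score, the expected change equals $\operatorname{var}_\phi p$
  (conditional) or
  $\mathbb{E}[\operatorname{var}_\phi p] + \mathbb{V}[\operatorname{ave}_\phi p]$
  (ensemble);
- **neutrality**: every selection quantity vanishes when genotypes do not
  affect phenotypes.

## Worked example

The built-in haplodiploid fixture has diploid females, haploid males, one
biallelic locus, two environments, and a class tally that fluctuates between
one and two females:

```r
library(rvprice)
model <- make_haplodiploid()
chain <- demographic_chain(model)
phi   <- solve_rv(model, chain)       # fixed point of T, two routes cross-checked
round(phi$values, 6)
#>                    F        M
#> e1::F=1,M=1 0.333333 0.333333
#> e1::F=2,M=1 0.166667 0.333333
#> e2::F=1,M=1 0.333333 0.333333
#> e2::F=2,M=1 0.166667 0.333333
```

These are per-haploid-set values $\phi^*$: at every state the ploidy-weighted
population sum is 1 (e.g. $2 \cdot 2 \cdot 1/6 + 1 \cdot 1/3 = 1$ with two
females), and females as a class carry $2/3$ of the gene pool — the
haplodiploid analogue of Fisher's equal-investment bookkeeping.

Switch on a selective phenotype map (females homozygous for allele *a*
get a fecundity and mating advantage) and look at one Taylor-year state:

```r
h   <- h_haplodiploid_selective()
pop <- apply_phenotypes(extract_population(c(`F|aa` = 1, `F|ab` = 1, `M|b` = 1)), h, model)
expected_fitness(model, "e1", pop, phi)
#>         phi     numerator expected_fitness  flag
#> 1 0.3333333  1.111111e-01     3.333333e-01 FALSE
#> 2 0.3333333 -1.111111e-01    -3.333333e-01 FALSE
#> 3 0.3333333  5.551115e-17     1.665335e-16 FALSE
```

The favoured female expects to grow her asymptotic gene-pool share by a
third; her rival loses a third; the male — whose chances are unchanged — has
expected fitness zero. The fundamental theorem then holds exactly at this
state:

```r
verify_ftns_conditional(model, h,
  list(env = "e1", tally = c(`F|aa` = 1L, `F|ab` = 1L, `M|b` = 1L)), phi)
#> <verification_report> ftns_conditional [exact]
#>   LHS 0.0185185185185185  RHS 0.0185185185185185  residual 3.469447e-18
```

and over the whole ergodic ensemble:

```r
D <- ergodic_distribution(ensemble_chain(model))
verify_price_ensemble(model, h, D, phi, c(a = 1, b = 0))
#> <verification_report> price_ensemble [exact]
#>   LHS 0.0027385439060167  RHS 0.00273854390601671  residual 1.864828e-17
```

so the expected change in the reproductive-value-weighted frequency of allele
*a* over the Taylor year (about +0.0027) equals the ensemble expectation of
its covariance with expected fitness.

A thin command-line driver over the same functions ships in
`inst/cli/rvprice.R` (`fixtures`, `solve-rv`, `simulate`, `verify`
subcommands), reading model files written by `write_model()`.

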