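---
title: "An equilibrium theory of the noncoding genome fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An equilibrium theory of the noncoding genome fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncodeq)
```

## The model

`noncodeq` studies how much phenotypically inert DNA a genome carries at
evolutionary equilibrium. The genome is an idealized circular haploid
chromosome of length $L = z_c + z_{nc}$ bp carrying $g$ identical, equally
spaced genes ($z_c/g$ bp each, the first base acting as promoter), separated
by identical intergenic tracts ($z_{nc}/g$ bp). Fitness is binary: deleting
any coding base, duplicating any promoter, or inserting material strictly
inside a gene is lethal; everything else is perfectly neutral. Mutations
initiate uniformly: each breakpoint of a structural event is an independent
uniform draw over the genome, so structural event sizes scale with genome
size — the property that ultimately drives the equilibrium.

Six mutation types are supported, each at per-base rate $\lambda_i \mu$:
duplications, deletions, inversions, point mutations, and small
insertions/deletions with sizes uniform on $1..l_m$ (default $l_m = 50$ bp).

### Neutrality combinatorics

Counting neutral breakpoint combinations under this measure gives exact
closed forms, e.g.

$$\nu_{del} = \frac{z_{nc}(z_{nc}+g)}{2\,g\,L^2}, \qquad
  \nu_{dupl} = \frac{(z_{nc}+z_c-g)(z_{nc}+g)}{2\,g\,L^2},$$

so $\nu_{del}/\nu_{dupl} = z_{nc}/(z_{nc}+z_c-g) \le 1$: duplications are more
often neutral than deletions, and conditional on neutrality they are larger on
average ($(p+1)/3$ vs $(m+2)/3$ bp, with $p = L/g$ the repeating unit and
$m = z_{nc}/g$ the intergene length). Neutral evolution alone therefore grows
the genome without bound. `neutral_prob()`, `neutral_prob_given_size()` and
`mean_neutral_size()` expose these quantities; `enumerate_neutrality()`
recomputes them by brute-force event enumeration on small genomes and
`sample_neutrality()` by Monte-Carlo on large ones.

### Robustness selection and fixation

A mutation that adds $k$ neutral bases still changes the carrier's *effective
fitness* $f_e$ — the probability that a reproduction event yields a viable
offspring — because a longer genome initiates more, potentially lethal,
structural mutations:

$$\log f_e = \sum_{t}\sum_{i=1}^{L}
  \log\!\big[(1-\lambda_t\mu) + \lambda_t\mu\,\nu_{t,i}\big],$$

with $\nu_{t,i}$ the neutrality probability of a type-$t$ event starting at
position $i$. Types are treated as independent, which is accurate whenever the
per-genome rate of neutral rearrangements is well below one. The selection
coefficient of a $+k$ change is $s \approx -2k\mu$ in the two-structural-type
model, and the fixation probability of a single mutant in a haploid
Wright–Fisher population of size $N$ is

$$P_{fix}(k) = \frac{1-r^2}{1-r^{2N}}, \qquad r = \frac{f_e(z_{nc})}{f_e(z_{nc}+k)}.$$

This is exactly the haploid Wright–Fisher diffusion fixation probability with
$s = \ln(1/r)$; the forward simulator `wf_fixation_mc()` therefore assigns the
mutant a sampling weight equal to the effective-fitness ratio itself, and the
squared exponents emerge from the diffusion.

### Flux balance and the equilibrium

Under the origination–fixation approximation (one mutant at a time, no clonal
interference), the expected fixed length flux of each size-changing type is a
sum over neutral sizes weighted by their multiplicity and fixation
probability, e.g.

$$\delta_{dupl} = \frac{g(z_{nc}+g)}{L^3}\sum_{j=1}^{p-1}(p-j)\,j\,P_{fix}(+j),
 \qquad
 \delta_{del} = \frac{g}{L^2}\sum_{j=1}^{m}(m-j+1)\,j\,P_{fix}(-j).$$

The bias $B$ is the ratio of shrinking to growing flux; the common
origination factor $\mu L N$ cancels, which is why $B$ — and hence the
equilibrium — depends on $N$ and $\mu$ essentially only through $N\mu$. In the
six-type model each flux is weighted by its rate multiplier; point mutations
and inversions do not change genome size and enter only through $f_e$ (their
multipliers never weight a flux; this composition choice is the package's
own, and point mutations provably leave every fixation probability
unchanged). `equilibrium_noncoding()` locates $B = 1$ by bisection; with only
short indels no such root exists — the insertion flux always dominates —
reproducing the conclusion that structural mutations are the ingredient that
makes a genome-size equilibrium possible.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `g` | number of genes | 2000 | reference prokaryote-like architecture |
| `zc` | coding size (bp) | 1e6 | 500 bp genes at `g = 2000` |
| `mu` | per-base per-type rate (/bp/gen) | 1e-10 | reference sweep value |
| `N` | population size | 1e8 | reference sweep value |
| `kappa` | deletion bias $\lambda_{del}/\lambda_{dupl}$ | 1 | unbiased mutational input |
| `lm` | max indel size (bp) | 50 | conventional indel/SV boundary |
| `bracket` | solver search interval (bp) | [1e3, 1e9] | spans the explored sweep |
| `tolerance` | relative tolerance on `znc` | 1e-6 | see below |

In the `kappa_rates()` parameterization the four size-changing multipliers sum
to 4 with $\lambda_{del} = \lambda_{indel-}$ and
$\lambda_{dupl} = \lambda_{indel+}$, and point mutations and inversions stay
at multiplier 1, so `kappa` moves the mutational input bias without changing
the total mutational load.

## Numerical contract

The per-position products in $\log f_e$ are never formed as products.
Positions group by symmetry into at most period-many classes per type, and
each class sum $\sum_{r\le n}\log(1+\beta r)$ is evaluated either exactly
(vectorized, when $n$ is small enough) or by a fourth-order power-sum series
in $\beta$, used only when $\beta(n+1) < 10^{-4}$, where its truncation error
(relative $\sim(\beta n)^3$) is far below double precision. Real-valued
(analytic-mode) noncoding sizes use the polynomial continuation of the power
sums.

Fixation ratios need $\log f_e(z_{nc}) - \log f_e(z_{nc}+k)$, a difference of
order $k\mu$ between numbers of order $L\mu$; direct subtraction would lose up
to nine digits at sweep scale. The difference is therefore assembled
analytically: the leading terms reduce to exact rational-function differences
of the form $-k\,(1 - c/(L(L+k)))$, and only the absolutely tiny higher-order
series remainders are differenced naively. $P_{fix}$ itself is computed as
`expm1(a)/expm1(N a)` with a log-scale route when $Na$ would overflow, the
neutral limit $1/N$ at $a = 0$, and never a silent infinity. Tests hold the
grouped evaluation to $10^{-12}$ relative agreement against an independent
per-position compensated (Kahan) summation on a fixed grid.

The solver bisects on $\log_{10} z_{nc}$ after verifying a sign change of
$B - 1$ and spot-checking monotonicity on a coarse grid; at relative tolerance
$10^{-6}$ on $z_{nc}$ the residual $|B(z^*_{nc}) - 1|$ lands below $10^{-6}$
at the reference parameters. A bracket without a sign change returns a
`converged = FALSE` result carrying the regime (growing/shrinking), never an
exception posing as a root — the indel-only model exercises this path by
design.

Sums over neutral sizes are evaluated exactly up to their architectural
limits (no truncation); at the top of the default bracket that means
$\sim 5\times10^5$ terms per flux, which is what bounds the solver's runtime
(well under a second per solve at reference parameters).

## Design choices where the design was open

* **Event measure.** A deletion is an ordered (start, size) pair, start
  uniform over the $L$ bases, size uniform over $1..L$; a duplication adds an
  independent uniform insertion junction; indels draw sizes uniform over
  $1..l_m$. This is the unique convention that reproduces the closed forms
  above and makes the raw expected size change of one mutation exactly zero
  (asserted by exhaustive enumeration in the tests).
* **Junctions.** The $L$ inter-base positions are the insertion/inversion
  breakpoints; a junction is "inside a gene" iff both flanking bases belong to
  the same gene, so exactly $z_c - g$ junctions are lethal and $z_{nc} + g$
  neutral — the $(z_{nc}+g)$ factor in the duplication flux.
* **Inversions.** Neutrality depends only on the two breakpoints; genes
  within a neutrally inverted segment are assumed re-orientable without
  effect (neutral inversions are also what justifies re-imposing the
  equal-spacing idealization after every size change). The closed form
  $((z_{nc}+g)/L)^2$ is a reconstruction from those counting rules and is
  validated against the event-level enumeration oracle, not against an
  external reference.
* **Indel cutoffs.** When the intergene length drops below $l_m$, neutral
  small-deletion counts truncate at zero rather than wrapping; the analytic
  continuation interpolates the fractional last position so the solver sees a
  continuous bias.
* **Expanded-model bias.** Flux weights use each type's own multiplier
  (they no longer cancel when rates differ); non-size-changing types
  contribute through robustness only.
* **Fixture generator.** Synthetic species tables sample $N_e\mu$
  log-uniformly over $[10^{-5}, 10^{-1}]$ — the range where the default
  bracket contains the equilibrium — and $N_e$ log-uniformly over
  $[10^5, 10^9]$, mirroring the explored parameter space. Observed fractions
  are the model's own predictions times lognormal noise, so they emulate the
  *shape* of a real compilation (monotone trend, scatter) but none of its
  biology: no functional noncoding DNA, no annotation error, no phylogenetic
  correlation. Passing overlay tests shows the pipeline is self-consistent,
  not that real genomes obey the model.

## What the simulations do and do not show

`wf_fixation_mc()` is quantitative: its empirical fixation rates match the
analytic $P_{fix}$ within binomial error and pin down the sampling-weight
convention. `wf_genome_trajectory()` is qualitative by construction: it runs
at tiny $N$, short genomes and inflated $\mu$ so that events occur at desk
scale, and it only checks that the population-mean noncoding size drifts in
the direction of $\mathrm{sign}(1 - B)$ and is stationary without mutations.
It does not estimate the equilibrium location — at such scales drift noise
and the rejection-sampling viability filter dominate.

Problem sizes used by the test suite and the acceptance script are desk
scale throughout: enumeration oracles run on genomes of tens of bases
(duplication spaces of at most $200^3$ events), Monte-Carlo fixation uses
$N = 50$ with $10^5$ replicates, and solver checks sweep $z_{nc}$ over
$10^3..10^9$ bp at the reference coding architecture.

## Known limitations

* The asymptotic fixation form $(1-e^{4k\mu})/(1-e^{4Nk\mu})$ (the displayed
  numerator is taken in the sign-consistent $1-e^{4k\mu}$ form) neglects the
  neutrality corrections to the effective-fitness gradient, of relative size
  $\sim z_{nc}/(gL)$; on the deleterious side that error is amplified by
  $e^{Na}$, so agreement with the exact form is $10^{-4}$-tight only in the
  weak-selection regime $|4Nk\mu| \lesssim 1$. The exact form is used
  everywhere in the pipeline; the asymptotic one exists for the
  $N\times\mu$-invariance analysis.
* $B$ is invariant under $(N,\mu)\to(cN,\mu/c)$ only up to $O(k\mu)$ curvature
  terms; at the reference $\mu = 10^{-10}$ the residue is $\sim 2\times10^{-7}$
  relative.
* Binary fitness, haploidy, no recombination, no transposable elements, no
  functional noncoding DNA, fixed coding architecture, uniform size
  distributions; the equilibrium's existence is robust to these, its location
  is not.
* The default bracket $[10^3, 10^9]$ bp caps solvable fractions at about
  $0.999$ (and floors them near $10^{-3}$); strong deletion bias at large
  $N\mu$, or no bias at very small $N\mu$, pushes the root outside and is
  reported as non-convergence rather than extrapolated.

## A worked example

```{r example}
rates <- mutation_rates(mu = 1e-10)          # two structural types, unbiased
eq <- equilibrium_noncoding(zc = 1e6, g = 2000, rates = rates, pop = 1e8)
eq
```

```{r curve}
equilibrium_curve(n_mu = c(1e-3, 1e-2), kappa = c(1, 10))[,
  c("N_mu", "kappa", "znc_star", "fraction_star", "converged")]
```
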