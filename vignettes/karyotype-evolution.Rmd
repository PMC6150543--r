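---
title: "Markov-chain models of karyotype evolution under chromosome missegregation"
author: "karyoMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-chain models of karyotype evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoMC)
```

## The model

Cancer cells with numerical chromosomal instability missegregate whole
chromosomes during mitosis: with probability $p$ per chromosome copy per
division, both copies of a replicated chromosome go to the same daughter
cell, so one daughter gains a copy and the other loses one.  A cell dies
when it loses all copies of any chromosome (nullisomy) or accumulates
more than $N$ copies of one.  `karyoMC` implements the absorbing Markov
chain that describes the copy number of one chromosome along a random
cell lineage (one random daughter followed at each division), and builds
everything else — karyotype distributions, population sizes, diversity —
from products of 23 such chains, one per human chromosome.  Independence
of missegregation events across chromosomes makes the product exact, so
the $N^{23}$ joint karyotype space never has to be enumerated.

Three simplifications, inherited from the underlying stochastic model,
shape the transition matrices:

1. chromosomes are treated one at a time (the product construction);
2. a single random daughter is followed at each division, which turns
   the branching population into a Markov chain whose
   conditional-on-viable law equals the population fraction law;
3. the probability that two or more copies of the same chromosome
   missegregate in one division, which is $O(p^2)$, is neglected.

Under these, the **basic chain** on states $1..N$ has
$M_{ii} = 1 - ip$, $M_{i,i\pm1} = ip/2$, with the remaining mass (from
states $1$ and $N$) flowing to the absorbing dead state.  `basicChain()`
stores the $N \times N$ block together with an explicit per-state death
mass, so each row sums to one exactly; spectral work happens on the
sub-stochastic block, which is what the theory needs, while conservation
stays checkable.  The simulator `simulateLineages()` can also run the
unlinearised binomial division rule, which quantifies simplification 3:
the one-generation deviation is $O\!\left(\binom{i}{2}p^2\right)$,
negligible at observed missegregation rates ($10^{-4}$–$10^{-2}$).

## Limiting distributions

Because death is certain in the long run, the interesting limit is the
distribution *conditional on viability*: the quasi-stationary
distribution, i.e. the left Perron eigenvector $\mathbf v$ of the
non-absorbing block, normalised to sum 1.  Writing $M = I + pJ$ with the
tridiagonal drift generator $J$ ($J_{ii} = -i$, $J_{i,i\pm1} = i/2$)
shows that $\mathbf v$ is an eigenvector of $J$ and hence *independent
of $p$* — only the speed of approach depends on $p$.

The package computes $\mathbf v$ two ways and cross-checks them in its
tests:

* **Closed form** (`limitingBasic()`, `limitingScored()`): the
  characteristic polynomials $P_n$ of the leading principal minors obey
  a three-term recurrence, and
  $v_i \propto \frac{2^{i-1}}{i!} P_{i-1}(\alpha)$ with $\alpha$ the
  largest root of $P_N$.  The basic recurrence is
  $P_n(x) = (x+n)P_{n-1}(x) - \frac{n(n-1)}{4}P_{n-2}(x)$; the *minus*
  sign follows from expanding the tridiagonal determinant along its last
  row, and is pinned by a unit test that reproduces the degree-8
  polynomial exactly (constant term $2835/2$).  For the score chain the
  recurrence gains $\mu$-dependent coefficients and the eigenvector
  formula acquires $p^{i-1}\mu^{(i^2+i-2)/2}$ **in the denominator** —
  the placement follows from the general tridiagonal eigenvector formula
  $v_i = b\,P_{i-1}(\lambda)/\prod_{j=2}^{i} a_{j,j-1}$ with
  sub-diagonal entries $a_{j,j-1} = jp\mu^j/2$, and is confirmed
  numerically by the eigensolver route.
* **Dense eigendecomposition** (`quasiStationary()`): base `eigen()` on
  the transposed block, with sign normalisation; kept as the production
  route for the extended chains and as the independent oracle for the
  closed forms.

Root finding for the closed form uses the Sturm property of the minor
sequence (the matrices are diagonally similar to symmetric tridiagonal
ones, so the spectrum is real and simple): bisection on the sign-change
count inside a Gershgorin bracket isolates the $k$-th largest root, and
a few Newton steps on the recurrence polish it to machine precision.
The minor sequence is evaluated with log-space rescaling, which keeps
the formula usable at $N = 200$ and beyond, where $i!$ and $P_{i-1}$
individually overflow.

Polynomial *coefficients* (as opposed to pointwise values) are only
materialised by `charPolyBasic()` / `charPolyScored()`.  For the basic
recurrence all coefficients are dyadic rationals, which IEEE doubles
represent exactly up to $N = 26$; the function refuses larger $N$ rather
than silently rounding, since nothing downstream needs expanded
coefficients at large $N$.

## Chromosome scores, and two further extensions

In the full model a cell's survival also depends on its karyotype
through per-chromosome scores $s_k$ (positive for chromosomes enriched
in oncogenes, negative for tumor-suppressive ones): each generation the
cell survives with probability $Q_{surv} = e^{c + d\sum_k s_k n_k}$,
with fitted constants $c = -0.036132164$ and $d = 0.00039047$ shipped
with the package (`hg23Scores()`, 23 rows, sex chromosome scored 0).
$Q_{surv}$ factorises as $\prod_k q_k(n_k)$ with $q_k(i) = C_k\mu_k^i$,
$\mu_k = e^{d s_k}$, which keeps the product-chain construction intact:
each chromosome's chain becomes $A = DM$ with $D_{ii} = q_k(i)$.

The split of $c$ into per-chromosome constants $C_k$ is arbitrary —
every split summing to $c$ yields the same product law, and all
conditional quantities are $C$-independent (tested).  The package
defaults to a split that keeps every $q_k(i) \le 1$, so the factors are
genuine probabilities and the per-chromosome chains are sub-stochastic;
the even split $c_k = c/23$ is also available but pushes $q_k(i)$ above
1 for the strongest oncogenic chromosome at $N = 8$, in which case the
builders warn and the death mass of the affected rows goes negative
(the row-conservation identity still holds).  A pleasing check: $c$
equals $-d \cdot \max_{\text{karyotype}} S$ to $4\times10^{-10}$, i.e.
the constant sits exactly at the largest value for which $Q_{surv}
\le 1$ on all valid karyotypes.

**Whole-genome duplication** (`duplicationChain()`) adds a transition
$i \to 2i$ with probability $p_{gd}/2$ (to death when $2i > N$, plus
$p_{gd}/2$ to death for the daughter that is never created).  $p_{gd}$
may vary by copy-number state, which expresses rate increases once a
chromosome reaches a copy-number threshold.

**Early tumor growth** (`inactivationChain()`) prepends two states to
the score chain for the phase in which aneuploidy is still lethal
because a gating gene (p53-like) is active: $\sigma$ (two active
copies) and $\tau$ (one active, one mutated).  While active copies
remain, any missegregation among the cell's 46 chromosome copies kills
it, hence the $(1-p)^{46}$ factor in those rows; active copies mutate
at rate $m_r$, and from $\tau$ a missegregation of the single active
copy can drop the cell into the tolerant states.  The transition matrix
is implemented exactly as the model defines it; note that it carries no
transition for missegregation of the *inactive* copy from $\tau$
(toward a one- or three-copy state that still has an active copy) —
a linearisation the package reproduces verbatim rather than repairs.
With $m_r > 0$ the $\sigma/\tau$ block is transient, so Perron theory
for irreducible chains does not directly apply; `quasiStationary()`
therefore returns the eigenpair with a `reducible` flag instead of
failing.  `timeToInactivation()` reports when the viable population
first becomes majority-tolerant; the proportion is read
conditional-on-viable (consistent with every other summary), with the
unconditional reading available via a flag.

## Dynamics, population size, diversity

`propagate()` renormalises the state vector every generation and
accumulates $\sum_g \log(\text{step survival})$, so trajectories are
well-defined to $10^6$ generations; when only the final generation is
needed and $g > 10^4$, matrix powers by repeated squaring (with the
same log-space scaling) are used instead.  Both routes agree to
$10^{-10}$ where they overlap (tested).

The surviving fraction $s_g(i)$ — the founder-row sum of the $g$-th
matrix power — gives the expected viable population
$2^g\prod_k s_g^{(k)}(f_k)$ (`expectedPopulation()`, log scale), and
the karyotype diversity index
$K = -\sum_{k}\sum_{j} a_{k,j}\ln a_{k,j}$ (`diversityIndex()`) sums
the Shannon entropies of the per-chromosome viable copy-number
fractions, so $0 \le K \le 23\ln N$.  `diversitySurface()` maps
$K(g, p)$; `optimalP()` maximises surviving fraction, $K$, or their
product over $p$ by grid search with golden-section refinement on
$\log p$ (ties to the smaller rate).  With the human scores and a
4-copy founder, the survival-optimal rate after 1000 generations falls
just under $10^{-3}$ and decreases slowly with $g$ — the regime of
missegregation rates actually observed in cancer cell lines.

## The stochastic oracle

`simulateLineages()` simulates the branching process directly (one
random daughter per division) for every chain kind, including the
full 23-chromosome karyotype with joint survival $Q_{surv}$.  It is
deliberately written against the *process* description, not the
matrices, so it is an independent oracle: the test suite compares
one-generation outcome frequencies against every row of every built
matrix kind (multinomial goodness-of-fit, $10^5$ lineages), long-run
conditional distributions and surviving fractions against the chain,
and the binomial against the linearised division rule.  Runs are
reproducible bit-for-bit from their seed (R's default Mersenne–Twister
generator).

One estimator needs more than raw lineage sampling: the time to
gating-gene inactivation occurs around generation $10^2$ at realistic
parameters, by which point a raw lineage survives with probability
$\sim 10^{-5}$.  `simulateInactivationTime()` therefore uses
Fleming–Viot resampling — dead lineages are respawned as copies of
uniformly chosen survivors — whose empirical distribution estimates the
conditional-on-viable law; with $2\times10^4$ particles it matches the
deterministic hitting time to within one generation.

## Numerical choices and defaults

* $N = 8$ is the default viability bound, the value used throughout the
  model's published analyses; the limiting distribution depends on it
  strongly (the one-copy fraction falls from 0.274 at $N=8$ to 0.013 at
  $N=200$), so it is an explicit parameter everywhere.
* $p \le 1/N$ is enforced as a hard error: beyond it the linearised
  diagonal $1 - ip$ goes negative and the matrix is no longer
  sub-stochastic.  The offending states are named in the error.
* Modal copy numbers break ties toward the smaller copy number
  (relevant only at knife-edge parameters).
* $\tilde\rho$ is the second-largest eigenvalue *modulus* of the
  non-absorbing block; the mixing estimate is
  $(1 - \tilde\rho/\rho)^{-1}$.
* Eigenvectors from `eigen()` are sign-normalised; a Perron vector with
  genuinely mixed signs raises an error, zero entries set the
  `reducible` flag.
* Reference tables from `referenceTables()` round to fixed reporting
  precisions (fractions 5 decimals, means 4, grid means 3) so the
  files serve as stable regression fixtures.

Test problem sizes are chosen to keep the full suite fast while still
exercising every regime: spectral cross-checks run at $N \le 16$ with
$N = 200$ as a scaling case, trajectory checks at $g \le 3000$ with a
$10^6$-generation underflow-safety case, and Monte-Carlo comparisons at
$10^4$–$10^5$ lineages, where binomial standard errors are small enough
to detect a wrong matrix entry at the third decimal.

## What the simulator does and does not emulate

The lineage simulator implements exactly the model's assumptions:
independent missegregation across chromosomes, memoryless per-generation
survival, synchronous generations, and (optionally) the linearised
division rule.  Passing tests therefore validate the implementation
against its own model, not the model against biology: real tumors have
overlapping generations, chromosome-specific missegregation biases,
correlated duplications (the model's genome-duplication extension treats
chromosomes independently and cannot capture their simultaneity), and
selection acting on more than chromosome dosage.  The model's authors
validated the modelling assumptions against experimental data
elsewhere; this package's claim is fidelity to the mathematics.

## Known limitations

* `charPolyBasic()` materialises exact coefficients only to $N = 26$
  (dyadic-rational exactness in doubles); pointwise evaluation, root
  finding and limiting distributions have no such cap.
* Per-state $p_{gd}$ applies to each chromosome's own copy number; the
  published copy-number-conditioned duplication example conditions on a
  specific chromosome, which a per-chromosome product chain can only
  track for that chromosome itself.
* The karyotype-level simulator supports scalar $p_{gd}$ only.
* Published reference values are reproduced to their supportable
  precision: a few last-digit discrepancies in the published tables
  (documented in the test comments) are on the order of $10^{-3}$ of a
  copy for grid means and $10^{-5}$ for distribution tails, and the
  package's two independent computation routes agree with each other
  to $10^{-9}$ or better in every such case.
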