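---
title: "Estimating the mutation history of tandem repeats with smtr"
author: "smtr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the mutation history of tandem repeats with smtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtr)
```

## The problem

Tandem repeats — stretches of DNA made of adjacent, approximate copies of a
short pattern — accumulate two kinds of mutations: tandem duplications,
which copy a substring and insert the copy immediately after its template,
and point substitutions, which degrade the periodicity the duplications
create. Because a repeat carries many copies of its pattern, a *single*
observed repeat sequence contains enough internal redundancy to say
something about its own history: how often mutations were substitutions
versus duplications of each length, and roughly how many mutations
occurred. `smtr` implements a generative model of this process, its
large-sequence limit theory, and the resulting inverse estimator.

## The model

A circular sequence $s$ over $\{A,C,G,T\}$ starts as a short *seed*
$s^{(0)}$ (for genomic repeats, the seed length is identified with the
pattern length $d$). At each step one mutation occurs:

* with probability $q_0$, a substitution at a uniform position, replacing
  the symbol by one of the other three uniformly;
* with probability $q_\ell$ ($\ell \ge 1$), a tandem duplication of length
  $\ell$: a uniform circular window of length $\ell$ is copied and the copy
  inserted right after the template.

$\mathbf q = (q_0, q_1, \dots, q_K)$ are *conditional* probabilities given
that a mutation happens — the estimator says nothing about chronological
rates. The sequence is circular so that there are no boundary effects;
linear genomic repeats are wrapped when their statistics are computed,
which biases the circular autocorrelation by $O(1/\text{copy number})$ —
one reason the estimator is unreliable at copy number $\le 3$ (see below).

The summary statistic is the normalized circular autocorrelation
$\rho^r = \frac1L\sum_{i=1}^L \langle s_i, s_{i+r}\rangle$ (indices mod
$L$), computed exactly via per-letter FFTs and integer rounding. It is
symmetric ($\rho^r = \rho^{L-r}$), so lags $0..\lfloor L/2\rfloor$ carry
everything and each value averages at least $L/2$ indicators.

## Limit theory

One mutation changes the expected match counts by a closed-form drift:
$-\frac83\rho^r + \frac23$ per substitution and
$r\rho^{r-\ell} + (\ell - r)\rho^r$ per length-$\ell$ duplication. Package
oracles (`oracle_substitution_drift()`, `oracle_duplication_drift()`)
recompute these expectations by exhaustive enumeration of every mutation
outcome; the test suite confirms that both closed forms are *exact* — for
substitutions over the full space of sequences up to length 6 (including
the boundary lag $r = L/2$, where no correction term appears), and for
duplications at every length once negative lags are read circularly on the
source sequence. The constants $8/3$ and $2/3$ are specific to a 4-letter
alphabet.

Averaging the drift over $\mathbf q$ and passing to the stochastic-
approximation limit gives a *linear* ODE for the profile,
$\frac{d}{dt}\boldsymbol\rho_t = A\boldsymbol\rho_t$, whose rate matrix
(`build_rate_matrix()`) has row 0 zero since $\rho^0 \equiv 1$. The
correspondence between discrete events and ODE time is
$t_n \approx \sum_{k<n} 1/L_k$, which grows only logarithmically in $n$ —
convergence in the number of mutations is therefore *polynomially slow*,
with exponent set by the spectral gap of $A$ divided by the mean length
gain. `profile_trajectory()` solves the ODE by matrix exponential; the
test suite checks simulated trajectories against it quantitatively.

Two regimes follow from the null space of $A$:

* **Pure duplication** ($q_0 = 0$): the limit set has dimension
  $\lfloor d/2\rfloor + 1$ where $d = \gcd\{\ell : q_\ell > 0\}$. The
  sequence becomes approximately periodic with period $d$ — the gcd, not
  the shortest or commonest duplication length (lengths $\{4,6\}$ give
  period 2). Lags divisible by $d$ are driven to 1; the other lags converge
  to seed-dependent mirror values, so the inverse problem is unsolvable in
  this regime. `null_space_basis()` computes the space numerically (SVD,
  rank threshold $10^{-10}$ times the top singular value) and
  `periodic_null_basis()` gives the analytic basis.
* **With substitutions** ($q_0 > 0$): the stationary profile with
  $\rho^0 = 1$ is unique, and every lag not divisible by $d$ sits exactly at
  $1/4$, the i.i.d. matching probability. `stationary_profile()` solves the
  bordered system (impose $\rho^0 = 1$, solve rows $1..m-1$ exactly) —
  deterministic, no eigen-iteration. For fidelity to the infinite system
  the window $m$ should exceed the largest duplication length $K$.

## The estimator

Rearranging $A\boldsymbol\rho_\infty = 0$ row by row turns the stationarity
condition into a linear system in the unknown probabilities,
$C'\mathbf q = \tilde{\boldsymbol\rho}$, with
$C_{r0} = \frac23 + (r - \frac83)\rho^r$, $C_{ri} = r\rho^{|i-r|}$ and
$\tilde\rho_r = r\rho^r$. The observed profile stands in for
$\boldsymbol\rho_\infty$, and the estimate is the constrained least squares
$$\hat{\mathbf q} = \arg\min_{\mathbf q}\ \|C'\mathbf q -
\tilde{\boldsymbol\rho}\|_2^2 \quad \text{s.t.}\ \textstyle\sum_i q_i = 1,\
q_i \ge 0,$$
solved with the dual active-set method of Goldfarb and Idnani
(`quadprog`), which is deterministic and reproduces exact solutions to
machine precision. The mutation count follows from length bookkeeping:
each mutation adds $\sum_{i\ge1} i\,q_i$ symbols on average, so
$\hat n = (L - L_0) / \sum_i i \hat q_i$ with $L_0 = d$ by default.

Choices that matter, with defaults and reasons:

* **Window rule.** $m' = m'' = \min(\max(10d, 5r^*), \lfloor L/2\rfloor)$,
  with $r^* = \arg\max_{r\ge1}\rho^r$ (first maximizer on ties —
  deterministic and favouring short periods). Large enough to cover the
  duplication support, small enough that every needed lag exists. With $d$
  unknown the same rule runs with $d = 1$.
* **Known pattern length.** When $d$ is known, duplication lengths are
  multiples of $d$; off-period profile values are replaced by their limit
  $1/4$ and only rows/columns with indices divisible by $d$ are kept. When
  $d$ is unknown the full design is used, and the smallest lag with
  $\rho > 0.8$ is reported as a *diagnostic* pattern-length suggestion
  only — it never enters the mathematics.
* **Expected-length constraint.** With $d$ known, the default adds
  $\sum_k (kd)\,q_{kd} \ge 1$, preventing $\hat q_0 \to 1$ from inflating
  $\hat n$ beyond the sequence length ($\hat n \le L - d$ follows). The
  constraint is a pragmatic device for observed data: it is *off* in the
  package's exact-inversion tests, because a true model may well gain less
  than one symbol per mutation on average, and forcing the constraint
  there would exclude the truth from the feasible set.
* **Regularization.** The Hessian $C'^TC'$ gets a relative ridge of
  $10^{-10}$ times its mean diagonal. For well-posed problems this
  perturbs the solution far below the reported precision (exact stationary
  profiles are recovered to $<10^{-6}$ in $L_2$ with residual
  $<10^{-10}$). For rank-deficient designs — a perfect repeat fits
  $C'\mathbf q = \tilde{\boldsymbol\rho}$ exactly with *any* duplication
  mix — it selects the minimum-norm solution, i.e. $\hat q_0 \approx 0$
  and near-uniform duplication-length probabilities, which is also the
  behaviour reported for perfect repeats in practice.
* **Low copy number.** The theory is asymptotic; at copy number $\le 3$
  the fit carries a structured warning (`smtr_low_copy_warning`) and a
  `low_copy_estimator` hook lets users plug in an alternative small-sample
  procedure without changing the interface. The default fit is still
  returned — nothing is substituted silently.

## What the simulator emulates, and what it does not

`evolve()`/`random_model()`/`random_seed()` are first-class, tested code:
they define the study conditions for every stochastic test. Defaults:
pattern length drawn uniformly from 1–10 (the length range associated with
polymerase slippage), seed length equal to the pattern length,
$q_0 \sim \mathrm{Uniform}[0, 0.5]$, and duplication mass spread over
$\{d, 2d, \dots, 5d\}$ by a symmetric Dirichlet — a neutral choice of
study conditions over multiples of the pattern, as observed duplication
lengths in genomic repeats are.

Real repeats differ from this model in ways the simulator deliberately
does not emulate: no insertions or deletions (hence the nonzero-indel
filter in preprocessing), unbiased substitutions (no
transition/transversion bias, no GC effects), duplication probability
independent of local heterogeneity, and a memoryless substitution process.
Passing tests therefore validate the estimator *under the model*, not the
model against biology.

## Simulation-study design

`run_recovery_experiment()` reproduces the parameter-recovery design: for
each mutation count $n$ on a grid, $N$ replicates draw a fresh
$(d, \text{seed}, \mathbf q)$ and $n_s$ sequences; estimates are computed
per sequence and then averaged (the averaging is over estimates, never
over autocorrelations). Reported metrics are the mean $L_2$ error
$\|\hat{\mathbf q} - \mathbf q\|_2$ and
$\mathrm{NRMSE}(n) = \frac1n\sqrt{\frac1N\sum_i(\hat n_i - n)^2}$. The
package's default grid is $n \in \{10, 50, 100, \dots, 500\}$ with
$N = 100$ and $n_s = 5$ — sizes chosen so the whole study runs in about
ninety seconds on one core while leaving the qualitative conclusions
(errors fall sharply in $n$; averaging five estimates helps) clearly
resolved. Both conclusions are asserted by the test suite on a fixed
master seed, and the harness is bit-reproducible given that seed.

```{r trend, eval = FALSE}
run_recovery_experiment(n_grid = c(50, 500), N = 100, n_s = 5,
                        rng_seed = 1)
```

## Numerical and degenerate cases

* Sequences are validated strictly: only `ACGT` (case-insensitive);
  N-containing repeats are removed upstream by `preprocess_repeats()`
  rather than silently recoded.
* Negative lags anywhere in the theory are resolved by the symmetry
  $\rho^{-k} = \rho^k$; this convention is set once and used everywhere
  (drift, design matrix, oracles).
* $q_0 = 0$ is a distinct regime with its own API
  (`null_space_basis()`); `stationary_profile()` refuses it rather than
  returning an arbitrary member of a multi-dimensional solution set.
* All stochastic functions accept an `rng_seed` argument that seeds a
  local RNG stream and restores the caller's stream, so library use never
  perturbs a user's global RNG state.
* Pure-duplication convergence is slow by nature: ODE time grows like
  $\log n$, so lag-$d$ autocorrelation approaches 1 at a polynomial rate
  in $n$ with a small exponent (for lengths $\{4,6\}$ the slow mode is
  $(\sqrt{17}-5)/2 \approx -0.44$, giving deficiency $\sim n^{-0.09}$).
  Tests of this regime therefore check agreement with the ODE trajectory
  and directional convergence, not proximity to the limit at finite $n$.

## Preprocessing of repeat catalogs

`read_trf_table()` parses Tandem Repeats Finder `.dat` output;
`preprocess_repeats()` applies the filters used before genome-scale
estimation: drop records with N bases, copy number $< 2$, or nonzero indel
percentage, then keep exactly one record per overlap cluster (any
intersection counts as overlap; the kept record is the highest-scoring,
ties broken by length then by earliest start — the catalog's own quality
score is the natural arbiter). Reverse complementation leaves the
autocorrelation profile unchanged (matching is preserved under both
reversal and complementation), so no strand handling is needed; the test
suite asserts this rather than assuming it.

## Known limitations

* No indels, biased substitutions, or heterogeneity-dependent duplication
  probability; no confidence intervals on $\hat{\mathbf q}$ or $\hat n$
  (no finite-time theory).
* The estimate conditions on mutation events; absolute rates per unit time
  are not identified.
* At copy number $\le 3$ the asymptotic premise fails; the package warns
  and exposes a hook rather than supplying a small-sample method.
* With $q_0$ estimated exactly 0 the history length is not identifiable
  (the pure-duplication degeneracy); the expected-length constraint keeps
  $\hat n$ finite but such fits should be read qualitatively.
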