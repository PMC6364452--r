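# smtr — mutation-history estimation for tandem repeats

Tandem repeats are genomic segments built from adjacent, approximate copies
of a short pattern. They grow by **tandem duplication** (a substring is
copied and the copy inserted immediately after its template) and are
degraded by **point substitutions**. Because one repeat contains many
copies of its pattern, a *single* observed sequence carries information
about its own history — no outgroup or second genome is needed.

`smtr` is for researchers studying repeat evolution: it provides the
generative model, its exact limit theory, and the inverse estimator that
recovers from one sequence

* the conditional mutation probabilities
  **q** = (q₀, q₁, …), where q₀ is the probability that a mutation is a
  substitution and q_ℓ that it is a duplication of length ℓ, and
* the total number of mutations n̂ in the sequence's history.

## Method in brief

The evolving sequence is modelled as circular; its normalized circular
autocorrelation ρʳ = (1/L) Σᵢ ⟨sᵢ, sᵢ₊ᵣ⟩ follows, in the large-sequence
limit, a linear ODE dρ/dt = Aρ whose rate matrix is determined by **q**.
With substitutions present (q₀ > 0) the stationary profile ρ∞ is unique,
equals 1/4 at every lag not divisible by the pattern length d, and
satisfies a linear system C **q** = ρ̃ in the unknown probabilities. The
estimator solves

&nbsp;&nbsp;&nbsp;&nbsp;**q̂** = argmin ‖C′**q** − ρ̃‖₂²  s.t.  Σ qᵢ = 1, qᵢ ≥ 0,

optionally with the constraint Σₖ (kd)·q_{kd} ≥ 1 (each mutation adds at
least one symbol on average), and then estimates the mutation count from
length bookkeeping: n̂ = (L − d) / Σᵢ i·q̂ᵢ. Under pure duplication
(q₀ = 0) the sequence instead becomes periodic with period gcd{ℓ : q_ℓ > 0}
— the gcd, not the commonest duplication length — and the inverse problem
is degenerate; the package exposes this regime through the null-space API.

## Worked example

Simulate a repeat from a known model (q₀ = 0.2, length-3 duplications with
probability 0.8), then estimate the history from the final sequence alone:

```r
library(smtr)
model <- mutation_model(c(0.2, 0, 0, 0.8))   # q0 = 0.2, q3 = 0.8
tr <- evolve(random_seed(3, rng_seed = 7), model, n = 400, rng_seed = 11)
length(tr$final)
#> [1] 987
fit <- smtr(tr$final, d = 3)
summary(fit)
#> SMTR estimate of tandem-repeat mutation history
#>
#> Sequence length: 987   pattern length: 3   copy number: 329
#> Window: m' = m'' = 30   (peak autocorrelation lag r* = 3)
#>
#> Estimated conditional mutation probabilities (q > 1e-8):
#>      0      3      6      9     15     24     27
#> 0.1641 0.7395 0.0054 0.0633 0.0038 0.0058 0.0181
#>
#> Estimated total mutations n = 280.68   (mean length gain/mutation = 3.506)
#> Least-squares residual: 0.006218
```

Reading the output: the substitution probability is estimated at 0.164
(truth 0.2) and the bulk of the duplication mass lands on length 3 (0.74,
truth 0.8), with small spillover onto other multiples of the pattern
length; n̂ = 281 against a true count of 400 — the count estimate is the
harder target and improves with longer histories. `coef(fit)`,
`coef(fit, "conditional")`, `fitted(fit)`, `residuals(fit)`,
`predict(fit)` (the implied asymptotic profile), `plot(fit)` and
`simulate(fit)` give the usual views of the fitted model.

For repeat catalogs, `read_trf_table()` reads Tandem Repeats Finder `.dat`
files and `preprocess_repeats()` applies the standard filters (no N bases,
copy number ≥ 2, zero indel percentage, one record per overlap cluster)
before estimation. A thin command-line front end with `simulate`,
`estimate`, `evaluate` and `preprocess` subcommands is installed at
`inst/cli/smtr.R`.

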