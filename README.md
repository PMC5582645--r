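# ratetoprob

Convert transition-rate matrices of multistate Markov models into
per-cycle transition-probability matrices — numerically, and symbolically
as spreadsheet-ready closed-form formulas.

## The problem

Medical decision models are usually multistate Markov models run in
discrete cycles, but their inputs are most naturally *transition rates*
(instantaneous intensities, e.g. from survival regressions or
proportional-hazards adjustments).  Going from the rate matrix `Q` to the
cycle-length-`t` probability matrix `P(t)` is a matrix-exponential
problem:

```
P(t) = Exp(Qt) = U Exp(Dt) U⁻¹        (Q = U D U⁻¹ diagonalizable)
```

The popular per-transition shortcut `p = 1 − exp(−q·t)` ignores the
possibility of two events in one cycle and is simply wrong whenever a
state has competing exits — it can even produce negative "probabilities".
This package is for analysts who need the correct conversion: either
computed numerically in R, or derived once as algebraic formulas (with
named intermediate variables that keep each formula short) and pasted
into the spreadsheet where the decision model actually lives, so that
age-group tables and probabilistic sensitivity analysis stay live in the
sheet with no copy-paste from external software.

For whom: health-economic modellers and biostatisticians working with
multistate cohort models, in R or in Excel.

## What it provides

* `rates_to_probs()` — eigen-decomposition conversion with automatic
  fallback to an independent series-summation matrix exponential, plus
  diagnostics for the failure modes (defective generators, nearly equal
  eigenvalues, complex pairs, out-of-bounds entries).
* `derive_formulas()` — symbolic five-step derivation (symbolic `Q` →
  characteristic roots → eigenvectors → inverse → `P(t)`) for an
  arbitrary allowed-transition structure, with intermediate variables;
  `export_spreadsheet()` writes the result as live A1-style formulas.
* `simple_probabilities()` / `competing_risks_probabilities()` /
  `compare_methods()` — the naive shortcuts and an error report.
* `rate_schedule()` / `markov_trace()` / `psa_draws()` / `psa_convert()`
  — per-age-group conversion, cohort traces, and PSA with
  flag-don't-drop degeneracy screening.
* a command-line tool (`inst/cli/ratetoprob`) wrapping the above:
  `convert`, `derive`, `compare`, `psa`, `trace`, `fixture`.

## Worked example

The classic three-state well/ill/dead model with all three rates 1 and
cycle length 1:

```r
library(ratetoprob)
Q <- read_rate_matrix(system.file("extdata", "three_state_rates.csv",
                                  package = "ratetoprob"))
rates_to_probs(Q, t = 1)$P
#> Transition-probability matrix, cycle length t = 1
#>        well    ill   dead
#> well 0.1353 0.2325 0.6321
#> ill  0.0000 0.3679 0.6321
#> dead 0.0000 0.0000 1.0000
```

A well patient has probability 0.135 of still being well after one
cycle, 0.233 of being ill, 0.632 of being dead — the exit probability is
large because the total exit rate from `well` is 2 per unit time.  The
naive per-transition formula on the same input shows why it cannot be
used with competing exits:

```r
round(compare_methods(Q, 1)$simple, 3)
#>        well   ill  dead
#> well -0.264 0.632 0.632
#> ill   0.000 0.368 0.632
#> dead  0.000 0.000 1.000
```

Both exit probabilities are inflated to 0.632 and the diagonal is forced
to −0.264, out of bounds.  The symbolic engine derives the correct
closed form for this structure:

```r
derive_formulas(struct_forward3(), naming = "qij")
#> Conversion formula set: 3 states, 8 intermediates
#> Eigenvalues:
#>   q11
#>   -q23
#>   0
#> ...
#>   p11(t) = exp(q11*t)
#>   p12(t) = exp(q11*t)*a'+q12*exp(-q23*t)*c'
#> ...
```

and `export_spreadsheet()` turns it into a CSV of live `EXP`/`SQRT`
formulas for Excel.

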