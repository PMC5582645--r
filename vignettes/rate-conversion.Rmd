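---
title: "Converting transition rates to transition probabilities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting transition rates to transition probabilities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratetoprob)
```

## The model

A continuous-time multistate Markov model with $n$ states is parameterized
by its transition-rate (generator) matrix $Q$: off-diagonal entries
$q_{ij} \ge 0$ are instantaneous transition intensities in events per unit
time, diagonals are $q_{ii} = -\sum_{j \ne i} q_{ij}$, so rows sum to zero.
Discrete-time cohort models need the per-cycle transition-probability
matrix $P(t)$ for cycle length $t$, which solves the Kolmogorov forward and
backward equations with $P(0) = I$.  Under the assumptions made throughout
this package — finite $n$ and a generator that is constant within a cycle —
the unique solution is the matrix exponential

$$P(t) \;=\; \mathrm{Exp}(Qt) \;=\; \sum_{r=0}^{\infty} \frac{Q^r t^r}{r!},$$

and when $Q$ is diagonalizable, $Q = U D U^{-1}$ with $D$ the diagonal
matrix of eigenvalues, this collapses to
$P(t) = U\,\mathrm{Exp}(Dt)\,U^{-1}$, where $\mathrm{Exp}(Dt)$ is diagonal
with entries $e^{d_{ii} t}$.

Everything in the package is one of two routes to this quantity, or
machinery around them:

* the **numeric engine** computes $U \mathrm{Exp}(Dt) U^{-1}$ from a
  floating-point eigen-decomposition, with an independent
  scaling-and-squaring series summation as oracle and fallback;
* the **symbolic engine** carries out the same derivation on a generator
  of named rate symbols, producing closed-form conversion formulas that
  can be pasted into a spreadsheet and re-evaluated per age-group or PSA
  draw without any matrix software.

## The symbolic derivation and its intermediate variables

Given only the allowed-transition structure, `derive_formulas()` performs
five steps: write the symbolic $Q$; solve the characteristic equation
$\det(Q - \lambda I) = 0$; solve $(Q - \lambda I)x = 0$ for each
eigenvector; invert $U$ via cofactors; and multiply out
$P(t) = U \mathrm{Exp}(Dt) U^{-1}$.  Directly expanded, the entries of
$P(t)$ become unusably long for $n \ge 4$, so after the eigenvalue,
eigenvector and inversion steps every composite entry is replaced by a
named *intermediate variable* — unprimed single letters for the eigenvalue
and eigenvector stages, primed letters for the inverse stage — and later
formulas are written in terms of those.  Each individual formula then fits
one spreadsheet cell.  The letters `e` and `t` are never used (they mean
the exponential and the cycle length); identical entries share one name;
and if a model exhausts the alphabet the engine switches to indexed names.

Design choices in this pipeline that the mathematics leaves open:

* **Diagonal entries stay symbolic.**  The generator is written with its
  own diagonal symbols (e.g. $a = -b-c-d$), whose definitions are recorded
  and evaluated first.  Substituting the definitions into the algebra
  would make the zero-eigenvalue eigenvector collapse to $(1,\dots,1)$ but
  blows up every other expression; keeping the diagonals atomic is what
  keeps the derived formulas short.  A single-exit row instead writes its
  diagonal directly as the negated exit symbol (`collapse_single_exit`),
  which removes a needless symbol.
* **Eigenvalue solving is structural.**  The strongly connected components
  of the transition graph put $Q$ in block-triangular form: singleton
  blocks contribute their diagonal entry as an eigenvalue; $2 \times 2$
  blocks contribute the quadratic-formula pair
  $(\mathrm{tr} \pm \sqrt{\mathrm{tr}^2 - 4\det})/2$.  An irreducible
  block of size $\ge 3$ leaves a residual characteristic factor of degree
  $\ge 3$; closed-form cubic and quartic solutions exist but are
  themselves tangles of intermediate variables, so the engine refuses
  (`rtp_unsolvable_characteristic`) and directs the user to the numeric
  route.  One consequence worth knowing: with positive rates a
  $2\times 2$ block's discriminant $(a-g)^2 + 4bf$ is never negative, so
  the formulas a derivable structure produces are always real-valued.
* **Eigenvector scaling.**  Any scalar multiple of an eigenvector works,
  so there are countless equivalent formula sets.  For reproducibility the
  engine always clears denominators by their polynomial least common
  multiple, divides by the greatest common divisor of the entries, and
  fixes the sign so the first nonzero entry has a positive leading
  coefficient.  The result can differ cosmetically (typically by an
  overall column sign) from hand-derived published sets; equivalence is a
  numerical fact, checked against the series oracle, not a textual one.
* **Root ordering.**  Nonzero eigenvalues come first, ordered by the
  lowest state index of the block that produced them (the $+\sqrt{}$ root
  before the $-\sqrt{}$ root); zero eigenvalues come last.  This matches
  the conventional layout in which the stationary direction sits in the
  last diagonal slot.
* **When to substitute the square root.**  The quadratic-pair symbols are
  introduced at the eigenvalue stage, but eigenvector entries that contain
  the root keep the explicit $\sqrt{\cdot}$ inside their own definitions
  rather than referring back to the eigenvalue symbols.  Substituting
  before or after scaling changes formula sizes in opposite directions
  depending on the model; the engine consistently scales first and leaves
  the radical explicit, which keeps every definition self-contained except
  for earlier intermediates.
* **Row-sum replacement is off by default.**  Replacing one entry per row
  by one minus the rest shortens the longest formula but makes it depend
  on the rest of its row; the library default keeps entries independent,
  and the option exists for spreadsheet users who prefer the shorter form.

The exact arithmetic underneath is a small in-package computer-algebra
layer: multivariate polynomials with integer/dyadic coefficients,
rational functions simplified by a primitive-PRS polynomial GCD, and a
quadratic extension symbol $s$ with $s^2 = \mathrm{disc}$ for the
square roots.  Dyadic rationals are exactly representable in doubles, so
all zero tests are exact; positivity of rate symbols is never assumed in
the algebra itself — structural zeros are literal zeros, and everything
else is treated generically.

## Numerical engine and failure modes

`probabilities_eigen()` computes the spectral route in complex arithmetic
and returns the real part; `probabilities_series()` computes
$\mathrm{Exp}(Qt)$ by scaling and squaring (scale $Qt$ by $2^{-s}$ until
its 1-norm is $\le 0.5$, sum Taylor terms until the next term's norm drops
below $10^{-14}$, square $s$ times).  Naive Taylor summation without
scaling loses accuracy once $\|Qt\|$ is large, which is why the scaling
step is not optional.  The series route has none of the eigen route's
failure modes and is used three ways: as the independent oracle in the
test-suite, as the cross-check inside `diagnose()`, and as the automatic
fallback of `rates_to_probs()` when the eigen route fails.

The failure modes, and how they surface:

* **Defective generator** (no eigen-decomposition): the eigenvector matrix
  is numerically singular; `eigen_decompose()` raises
  `rtp_not_diagonalizable` (condition number above $10^{12}$, or a
  repeated diagonal entry with coupling in the exactly-triangular branch)
  and `rates_to_probs()` silently switches to the series route, recording
  the fallback in its report.
* **Exactly equal eigenvalues**: the derived formulas divide by
  eigenvalue differences, so `evaluate_formula_set()` raises
  `rtp_degenerate_evaluation` on a division by zero, and the numeric
  route flags the repeat (raising only when the eigenvector matrix is
  also ill-conditioned, since a diagonalizable repeat — e.g. the zero
  generator — is numerically harmless).
* **Nearly equal eigenvalues**: catastrophic cancellation in those same
  denominators.  Doubles carry roughly 16 significant figures, so the
  report warns (`near_degenerate`) when two eigenvalues agree to more
  than 8 significant figures — the conservative end of the usual
  8-to-10-figure rule of thumb.  One refinement: a repeated *zero*
  eigenvalue caused by several absorbing states is structural, the
  formulas never divide by that difference, and it is excluded from the
  gap metric (an all-zero spectrum still counts as degenerate).
* **Complex eigenvalue pairs** (models with transition cycles): handled
  natively in complex arithmetic; the imaginary parts must cancel in
  $P(t)$ and the residual is recorded.  The spreadsheet exporter refuses
  rate sets that would make a `SQRT` argument negative, although, as
  noted above, no derivable structure produces one.
* **Out-of-bounds probabilities**: excursions beyond $[0,1]$ within
  $10^{-10}$ are treated as floating-point dust, clipped and the row
  renormalized; anything larger is left in place and reported, because a
  genuinely out-of-bounds value is a finding, not noise.  The threshold
  is a package choice: it is far above unit roundoff for these problem
  sizes and far below any scientifically meaningful violation.

## Naive formulas, schedules, and PSA

`simple_probabilities()` implements the per-transition shortcut
$p_{ij} = 1 - e^{-q_{ij} t}$ with the diagonal as row complement.  It is
exact only for a single exit into an absorbing state; with competing exits
its diagonal can go negative, and its error vanishes only as $O(t^2)$ when
cycles shrink.  `competing_risks_probabilities()` allocates the total exit
probability proportionally to the rates, which is exact precisely when
every successor of a transient state is absorbing; the classical
formulation treats one state with two competing absorbing exits, and the
implementation extends it to any number of competing absorbing exits
because the proportional-allocation derivation never uses the exit count.
`compare_methods()` runs all three against each other and tabulates errors
and bounds violations.

`rate_schedule()`/`convert_schedule()` convert age-varying rates cycle by
cycle, collecting per-cycle diagnostics and never letting one bad age-band
abort the rest.  `markov_trace()` propagates a row occupancy distribution
(cohort convention: row $k$ = row $k-1$ times the cycle-$k$ matrix).

PSA draws each transition rate independently from a distribution matched
by moments to the point estimate and standard error.  The default family
is lognormal, with gamma as the alternative; both guarantee positive
draws, which is why a normal family is not offered.  Correlation between
transitions (e.g. a shared hazard ratio) is not modelled: draws are
independent per transition.  Converted draws whose diagnostics flag
near-degeneracy or bounds violations are marked in the summary and kept —
discarding a few flagged draws is a defensible user decision, silently
dropping them inside the library is not.  Scatter data (eigenvalue gap,
bounds excursion, every probability, per draw) export as tidy CSV for
exactly that inspection.

## Spreadsheet export

`export_spreadsheet()` writes the derived formulas as a plain-text CSV of
live A1-style spreadsheet formulas using only arithmetic, `EXP` and
`SQRT` — no macros — which Excel and LibreOffice evaluate on import.
`matrix_blocks` lays the six matrices $Q, D, U, U^{-1}, \mathrm{Exp}(Dt),
P(t)$ side by side with each intermediate's defining formula in its home
cell and references elsewhere; `single_row` puts rate inputs, every
intermediate and every probability in one row, intended to be copied down
once per age-group or PSA draw.  Cell offsets within a layout are the
package's own convention.  The tests round-trip both layouts through an
independent A1-formula interpreter and compare against the series oracle.

## The synthetic fixture generator

`generate_fixture()` draws allowed rates uniformly from $[0.1, 2]$ per
unit time by default — the range where per-cycle transition probabilities
for annual-style cycles span the scientifically interesting region from
a few percent to near-certainty — and redraws (up to 100 times) while the
diagnostics flag the draw, so that default fixtures are well-conditioned;
a flag disables the redraw for stress fixtures.  What it emulates is the
*numerical* variety of generators of a given structure.  What it does not
emulate: empirical rate estimates (no censoring, no sampling error, no
covariate structure), correlated uncertainties, or time-varying rates
within a cycle.  Passing tests on these fixtures shows the conversions
are mathematically correct across the structure's parameter space, not
that any particular clinical model is well specified.

## Problem sizes and tolerances used in the tests

The equivalence suite derives formula sets for five canonical structures
(three-, four- and five-state models plus a six-state progression chain)
and checks formula evaluation and the eigen route against the series
oracle on 200 random rate assignments per structure at $10^{-9}$
elementwise; conservation and semigroup properties run on dozens of
random fixtures at $10^{-10}$/$10^{-9}$; the naive-formula convergence
check halves the cycle length over six decades and requires a log-log
slope in $[1.8, 2.2]$.  These sizes keep the full suite under a couple of
minutes on one CPU while exercising every code path; the mathematics does
not change at larger $n$ until the degree-cap refusal, which is tested
directly.

## Known limitations

* Characteristic factors of degree $\ge 3$ are refused, not solved; use
  the numeric route for models with longer transition cycles.
* The algebra layer's coefficients live in doubles; pathological
  structures could overflow the exact-integer range ($2^{53}$) during GCD
  computation, though none of the supported model sizes ($n \le 10$) come
  close.
* Time-inhomogeneity is supported only as piecewise-constant rates across
  cycles (schedules), not within a cycle.
* Cost/QALY accumulation, discounting and value-of-information analysis
  are downstream of the conversions and out of scope.
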