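---
title: "Random-walk models of sequential rating judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk models of sequential rating judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratingwalk)
```

## The problem

When people answer two related questions in a row — here, "how effective is
this public-service announcement *to you*?" and "... *to your friends*?",
each on a 9-point scale — the joint distribution of the two answers depends
on the order in which the questions are asked.  `ratingwalk` implements and
compares two process models of this phenomenon, both built on the same
anchoring-and-adjustment idea: the state reached while answering the first
question is the anchor from which the second answer is produced.

Both models live on a lattice of `N = n_ratings * states_per_rating` ordered
*evaluation states*; each observable rating owns a contiguous block of
`states_per_rating` lattice states (odd, so every block has a midpoint).
The default `lattice_spec()` uses 9 ratings times 11 states (`N = 99`,
neutral state 50).  The walk starts spread uniformly over the 11 states
centred on the neutral state.  The first rating is read out with diagonal
block projectors; the collapsed (un-normalised) state then evolves under the
second question's dynamics, which yields joint rather than conditional
probabilities.

## The two walks

**Markov birth–death walk.**  A continuous-time chain with generator
columns carrying rate `alpha` toward lower states and `beta` toward higher
states and reflecting ends; the transition matrix is `expm(K)` at unit time
(the processing-time parameter is absorbed into the rates, so fitted
intensities are in the hundreds).  Under this orientation an excess of
`alpha` over `beta` drifts the evaluation toward the low end of the scale,
which is the direction the study data require.  Self and other questions
each get their own rate pair, and — crucially — both questions share one
basis: after the first answer the chain simply keeps moving in the same
state space.

**Quantum walk.**  A tridiagonal "crystal" Hamiltonian with constant
coupling `alpha` on the off-diagonals and a linear potential `beta * i / N`
on the diagonal; the propagator is `expm(-1i * H)`, computed by spectral
decomposition of the real symmetric `H`.  Each question has its own basis.
After the first rating is measured (projective collapse within the first
question's basis) the amplitudes are carried back to the neutral basis by
the inverse unitary and only then rotated into the second question's basis.
This return through the neutral basis is the structural difference from the
Markov model and the source of its ability to fit both question orders with
one parameter set; the squared moduli of the between-question kernel are
doubly stochastic, a signature the Markov transition matrix does not share.

**Non-judgemental mixture.**  A fraction `1 - lambda` of trials bypasses
judgement entirely and answers the scale midpoint twice; `apply_mixture()`
adds that mass to cell (5, 5).  One shared `lambda` serves both orders, and
`lambda = 1` (mixture off) is available as a 4-parameter variant via
`walk_fit(..., lambda = 1)`.

### Conventions that matter

Several sign/index conventions are observationally constrained and fixed as
follows:

* Transition matrices are **column-stochastic** (`T[i, j]` is the
  probability of `i` given `j`); all operator products read right to left.
* In the Markov generator `alpha` occupies the **upper** off-diagonal,
  i.e. it drives the walk toward rating 1.  With the published intensity
  estimates (where `alpha > beta`) this reproduces marginal means just
  below the scale midpoint and the reported Markov fit quality; the
  opposite orientation does not.
* The quantum potential uses 1-based state indices, `beta * (i / N)` for
  `i = 1..N`, matching the lattice labels; a 0-based convention differs
  only by a global phase plus an `O(beta/N)` endpoint effect and is
  observationally negligible.
* Reflecting boundaries delete the outward rate in the generator's end
  columns (keeping column sums zero); the Hamiltonian band simply
  truncates.  Other reflecting conventions (e.g. extra self-loop mass)
  would shift fitted optima slightly.
* The initial amplitudes are real and equal; any global phase is
  unobservable.

### Lattice resolution

The 99-state lattice approximates a continuum.  Refining it (e.g. 21 states
per rating) reproduces the same predicted tables to within a few hundredths
per cell once parameters are rescaled by the refinement ratio `s`: quantum
`alpha` and the Markov diffusion rate `alpha + beta` scale by `s^2`, the
Markov drift `beta - alpha` by `s`, and potentials are unchanged.  The test
suite checks this as a smoke property.

## Estimation

`walk_fit()` estimates the four dynamic parameters plus `lambda` against
one or both order-conditioned tables, by either

* **SSE** — summed squared cell discrepancies, reported as
  `R^2 = 1 - SSE/TSS` with the total sum of squares around each table's own
  mean cell value; or
* **likelihood** — the multinomial log likelihood of the observed counts,
  reported as the `G^2` lack of fit against the saturated (cell-by-cell)
  model.  The saturated reference for two 9 x 9 tables has 160 free cell
  probabilities; the `G^2` value itself does not depend on how that
  bookkeeping is counted.

Markov rates are log-transformed (positivity), `lambda` is
logit-transformed, quantum parameters are unconstrained.  The objective is
cheap (two 99 x 99 matrix exponentials per evaluation) but multimodal —
strongly so for the quantum model, whose likelihood surface oscillates in
the coupling parameters.  Plain multi-start simplex search from
Latin-hypercube draws regularly stalls in local optima some 0.05–0.1 of
R-squared below the attainable fit, so the default optimiser adds a
deterministic screen that exploits a structural fact: the marginal
distribution of the *first* rating depends only on that question's two
parameters.  Each question's parameter pair is scored on a coarse 2-D grid
against its first-rating marginal, the best cells of the two questions are
crossed, and these informed starts are polished together with the seeded
Latin-hypercube starts by Nelder–Mead (the best few survivors twice).
Polish depth is model-aware by default: every candidate is polished for the
quantum walk (cheap evaluations, many basins), the best ten for the Markov
walk (costlier matrix exponentials, a well-behaved surface).  The grid
stage is deterministic, so the fits it wins are identical for every seed,
and the whole procedure is deterministic given `walk_fit_control(seed = )`.
Default search boxes: rates 1–1000 (log-spaced), quantum coupling 1–300,
potential slope −100–100, mixture weight 0.5–1.

Degenerate inputs are handled conservatively: probability tables must sum
to one within `1e-10`; model probabilities are floored at `1e-12` inside
`G^2`; zero observed cells contribute nothing; roundoff-scale negative
entries of the Markov matrix exponential are clipped to zero.

## The order-effect test

`order_effect_test()` compares the saturated two-table multinomial model
against the restriction that one joint distribution generated both orders
(`G^2` with `df = 80` for 9-point scales).  Two caveats are inherited from
the design and reported rather than corrected: trials pooled over
participants and stimuli are not independent, and with ~780 trials spread
over 81 cells the chi-square reference is only roughly calibrated — the
suite shows the nominal 5% level is attained in the large-count regime
(100x the study size) but overshoots (~7%) at the study's own size even
under a dense null, and undershoots badly under sparse nulls where the
nominal `df` overcounts never-observed cells.

## Synthetic experiments

`simulate_experiment()` emulates the study design: every participant rates
every stimulus once, each trial's question order is an independent
Bernoulli draw (0.5 by default, matching the randomised design that
produced 775 self-first / 797 other-first trials out of 131 x 12), and the
rating pair is a draw from the generating model's mixed joint table for
that order.  Defaults (131 participants, 12 stimuli) are the study's; a
single seeded stream, consumed order-then-ratings in record order, makes
runs bit-reproducible.  Participants are homogeneous and the stimulus
identifier is carried for record realism only — the models pool all trials,
so per-participant or per-stimulus effects are deliberately out of scope.
Consequently, passing recovery tests on these data show that the estimation
machinery inverts the models' own sampling process; they cannot certify
robustness to participant heterogeneity, stimulus effects, or response
habits present in real data.

Two recovery properties are exercised in the suite, scaled to keep the run
short: prediction-level recovery (refits to data simulated at 20x the study
size reproduce the generating tables with `R^2 > 0.98` — the parameters
themselves are only weakly identified, so recovery is asserted at the
prediction level), and model discrimination (likelihood fits of both models
to a handful of study-sized quantum-generated replicates prefer the quantum
model), using reduced optimiser settings (about a third of the default
starts) chosen to keep each fit a few seconds.

## What reproduces from the printed tables, and what cannot

The packaged observed tables are the published integer-percent cells.
Quantities that are smooth functionals of the tables reproduce essentially
exactly: forward-predicted means at the reference estimates (to within
0.01 of the published parenthesised values), 80 of 81 predicted self-first
cells after rounding, refit R-squared values (0.89 joint quantum vs the
published 0.90 computed on unrounded data; 0.55 joint Markov vs 0.54; 0.92
single-table Markov).  `G^2`-type statistics are *not* smooth in that
sense: they weight every cell by a log-ratio against probabilities as small
as `1e-4`, so integer rounding of 81-cell tables inflates them
substantially above the published raw-count values (order test ~190 vs
110.19; Markov lack of fit ~1650 vs 1190; quantum ~1195 vs 839 — note the
quantum/Markov ratio, 0.72, matches the published 0.71).  The package
computes these statistics honestly from the printed information and leaves
the discrepancy visible rather than massaging the reconstruction toward
the published numbers.  Similarly, participant-level mean-difference
statistics require raw per-person records that were never published, and
the other-first table's printed cells are internally inconsistent with the
published raw-data self mean in that order (3.77 vs 4.11), so
`order_effect_summary()` reproduces the self-first difference (0.52 vs the
published 0.50) and the direction of the interaction, but not the
other-first magnitude.
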