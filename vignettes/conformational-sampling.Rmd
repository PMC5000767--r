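---
title: "How many conformations? Methods behind qmmconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many conformations? Methods behind qmmconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmconverge)
```

## The model

Adiabatic QM/MM barrier calculations optimize a reaction path within one
frozen enzyme conformation.  Averaging over $n$ MD snapshots, the package
works with two statistics of the per-conformation activation barriers
$\Delta E_i$ (kcal·mol⁻¹, finite and strictly positive):

**Boltzmann-weighted average.**
$$\Delta E \;=\; -RT\,\ln\!\Big[\tfrac{1}{n}\sum_{i=1}^n
\exp\!\big(-\Delta E_i/RT\big)\Big]$$
This is the exponential average of the barriers; it always lies between
$\min_i \Delta E_i$ and the arithmetic mean (Jensen's inequality),
approaching the minimum as $T\to 0$ and the mean as $T\to\infty$.  It is
the physically motivated summary when the sampled conformations feed a
single rate-determining step: the lowest barriers dominate the rate.

**Disproportionate effect.**
$$DE \;=\; 100\,\frac{\Delta E^{a-l}-\Delta E^{a}}{\Delta E^{a}}\;\%$$
where $\Delta E^{a-l}$ recomputes the Boltzmann-weighted average with the
single lowest-barrier conformation removed.  $DE \ge 0$ always.  A large
$DE$ means the average is carried by one anomalously low barrier — the
characteristic signature of under-sampling, since the exponential average
gives such a conformation disproportionate weight.

**Assumptions.** Snapshots are treated as independent draws from the
conformational ensemble (no autocorrelation correction); barriers are
positive; one barrier per conformation (single rate-determining step);
energies are plain potential-energy barriers (no free-energy, zero-point
or tunnelling corrections).

## The convergence rule

Both statistics are tracked as *running* (prefix) series in sampling
order: the Boltzmann average from $n = 1$, $DE$ from $n = 2$ (its first
defined prefix).  The rule declares the estimate at prefix length $n^*$
converged when the changes produced by the next `window` additions all
stay **strictly below** `threshold`.  Demanding a full window of
subsequent stability guards against freezing on a momentarily quiet
series that has not yet seen its low-barrier conformations.

Tunable parameters of `convergence_rule()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold` | 5 | % (relative metric) | conventional "few percent" stability demand; 0 yields a rule that never fires, forcing exhaustive evaluation |
| `window` | 5 | additions | long enough that a single lucky draw cannot confirm convergence |
| `metric` | `relative` | — | both statistics have natural scales; see below |
| `denominator_floor` | 1e-8 | statistic units | keeps the relative change finite when the previous value is ~0 (possible for $DE$) |
| `semantics` | `window_start` | — | which count is reported; see below |

Two genuinely open choices are exposed rather than hidden:

* **Change metric.** "Change less than 5%" is interpreted as percent
  change relative to the previous prefix value, uniformly for both
  statistics.  For $DE$ — itself a percentage that can sit near zero —
  relative change is unstable, hence the `denominator_floor` and the
  `absolute` option (percentage-point changes).
* **Window semantics.** A converged-after count can index the start of
  the confirmed window ($n^*$: the estimate the window vouches for) or
  its end ($n^* + window$: when confirmation completes).  The default is
  `window_start`; both are one flag away, and the acceptance tests sweep
  both where published counts are compared.

The combined criterion (`combined_converged_after()`) is the maximum of
the two converged-after counts — both statistics must be stable — and is
`NA` whenever either never settles within the series.  Because the count
depends on the arbitrary MD sampling order, `ordering_sensitivity()`
reports its distribution over seeded permutations.

**Temperature.** The thermal energy $RT$ uses $T = 298.15$ K and
$R = 1.987204\times10^{-3}$ kcal·mol⁻¹·K⁻¹ by default — standard
laboratory conditions — and is overridable everywhere
(`thermal_context()`).  Published analyses of this kind often omit the
temperature used; any quantitative comparison should sweep plausible
values (the acceptance tests use 293.15, 298.15, 300 and 310 K).

## The screening protocol

Small-QM-region barriers are cheap and inaccurate; big-QM-region barriers
are expensive and accurate; empirically the two are positively (if only
roughly) rank-correlated.  `run_protocol()` exploits this:

1. pre-screen all $n$ conformations with the small QM region;
2. rank conformations by small-QM barrier, lowest first
   (`rank_by_small()`, stable on sampling order for determinism);
3. evaluate big-QM barriers in that order, re-checking the combined
   criterion over the big barriers evaluated so far after each addition;
4. stop at the first count where the criterion fires; if it never does,
   evaluate all $n$ (the result then equals the full-set statistics
   exactly).

Convergence inside the protocol is judged on the ranked evaluation order —
the only sequence that exists while evaluations accrue.  Since the
Boltzmann average is dominated by the lowest barriers and those are
front-loaded, the subset estimate approaches the full-set value from
below quickly when the correlation is decent; worse correlation costs
more big-QM evaluations but does not bias the endpoint, because the
stopping rule only fires when the estimate stops moving.  The criterion
is re-evaluated from scratch at each addition; at these problem sizes
(tens of conformations) streaming would save nothing measurable.

**Cost accounting.** In big-QM-evaluation equivalents, with
`relative_cost` $c$ (default 0.1, i.e. a small-QM evaluation at 10% of a
big one):
$$\mathrm{savings} = 100\cdot\frac{\mathrm{baseline} -
(n\,c + n_\mathrm{big})}{\mathrm{baseline}}\;\%$$
The default baseline is evaluating all $n$ conformations with the big QM
region; it is configurable because a fair baseline can also be the number
of conformations the non-protocol analysis actually needed.  Savings can
be negative: pre-screening at high relative cost plus many big-QM
evaluations exceeds the baseline.  For orientation, $n = 20$, $c = 0.1$,
$n_\mathrm{big} = 8$ gives exactly 50% savings.

`barrier_correlation()` defaults to Spearman rank correlation
(average-rank ties) because the protocol only relies on an approximately
monotone relation, not linearity; Pearson is available as an option.

## The synthetic generator

`generate_paired_ensemble()` emulates the data structure the method
consumes: $n$ snapshots on a fixed time grid (defaults: 20 snapshots at
0.5 ns, spanning 10 ns) whose (small, big) barrier pairs are drawn from a
bivariate normal with rejection of non-positive draws.  Defaults — means
22 and 16 kcal·mol⁻¹, spreads 3 kcal·mol⁻¹, latent correlation 0.7 — were
chosen once as representative of enzymatic dehalogenation barriers
(small-QM values clustering near 20 kcal·mol⁻¹ with the region's known
bias upward relative to big-QM values, spreads of a few kcal·mol⁻¹, and a
clearly positive but imperfect small/big relation).  A log-normal family
(moment-matched, correlated on the log scale) is available for skewed
ensembles.  One integer seed determines the entire stream, and the
caller's RNG state is left untouched.

For a bivariate normal, the population Spearman correlation is
$\tfrac{6}{\pi}\arcsin(\rho/2)$; the tests verify the generator recovers
this within sampling error across seeds.

What the generator deliberately does **not** emulate: autocorrelation
between successive snapshots (real MD frames 0.5 ns apart may not be
independent), multi-modal conformational basins, skew/heavy tails beyond
the log-normal option, or any structure–energy relationship.  Passing
tests on synthetic data therefore demonstrate the statistics, rules and
protocol machinery — not that 20 snapshots suffice for any particular
enzyme.

## Numerical choices and degenerate inputs

* The Boltzmann average is evaluated as
  $m - RT\ln\big[\tfrac1n\sum_i e^{-(\Delta E_i - m)/RT}\big]$ with
  $m = \min_i \Delta E_i$ (log-sum-exp), so barriers of several hundred
  kcal·mol⁻¹ cannot underflow; tests pin it to a naive direct-summation
  oracle to $<10^{-10}$ relative error.
* Ties for the lowest barrier (in $DE$ and in `min_barrier()`) drop or
  report exactly one record, the earliest in sampling order —
  deterministic and order-stable.
* Ties in the protocol ranking keep sampling order (stable sort).
* A trace too short to host a full window after any candidate returns
  `NA`, never a guess; `NA` propagates through the combined criterion.
* Barriers must be finite and strictly positive (the $DE$ denominator is
  a Boltzmann average of them); violations error at construction with
  named messages, as do empty ensembles, duplicate conformation ids,
  non-positive temperatures, and unparsable table cells (named by row and
  column).
* Generator parameters that make positive draws practically impossible
  (e.g. negative mean with near-zero spread) error after a bounded number
  of rejection batches rather than looping.

## Problem sizes

The test suite and the reproduction script run at the scale the method is
designed for: ensembles of 1–100 conformations, property batches of
10²–10³ random ensembles, synthetic moment checks at $n = 10^4$,
correlation-recovery checks at $n = 2000$ over 20 seeds, and a 60-snapshot
series with 50 permutations for the ordering-sensitivity analysis.  The
full suite completes in well under a minute.

## Known limitations

* The package analyses barrier tables; it does not perform or validate
  the QM/MM calculations that produce them, and it cannot detect biased
  sampling upstream (e.g. a trajectory that never visits a low-barrier
  basin — the disproportionate effect only flags the low barriers the
  sample *contains*).
* The convergence rule is a stopping heuristic, not a statistical test:
  it controls the stability of the estimate, not its distance from the
  infinite-sampling limit.
* Per-conformation barrier tables from published FAcD dehalogenation
  studies are not redistributed with the package; the bundled paired
  table is synthetic — produced by `generate_paired_ensemble(synthetic_spec(seed = 20))`
  — and labelled as such in its filename.  Users with published or in-house
  tables can load them unchanged via the documented TSV schema, extra
  columns included.
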