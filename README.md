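# qmmconverge

Convergence diagnostics and efficient conformational sampling for QM/MM
barrier averaging.

## The problem

Adiabatic QM/MM (e.g. DFT/MM) calculations of enzymatic reaction barriers
optimize a reaction path inside one fixed enzyme conformation.  A single
MD snapshot gives biased energetics, so practice is to extract many
snapshots, compute one activation barrier ΔE<sub>i</sub> (kcal·mol⁻¹) per
conformation, and average.  Each barrier costs hours to days of QM/MM
compute, so the practical question is: **how many conformations are
enough, and can cheap calculations tell us which ones to spend the
expensive ones on?**

`qmmconverge` is for computational enzymologists who have (or will have)
per-conformation barrier tables and need a defensible stopping rule and
screening strategy.  It implements:

1. **Boltzmann-weighted (exponential) average barrier**

   ΔE = −RT ln[ (1/n) Σᵢ exp(−ΔEᵢ / RT) ]

   evaluated with a log-sum-exp shift so large barriers never underflow.
   Low-barrier conformations dominate this average, matching the physics
   of a rate-determining step.

2. **Disproportionate effect (DE)** — the percent rise of that average
   when the single lowest-barrier conformation is excluded:

   DE = 100 · (ΔE<sup>a−l</sup> − ΔE<sup>a</sup>) / ΔE<sup>a</sup>

   A large DE means one anomalously low barrier is carrying the average:
   a red flag for under-sampling.

3. **Windowed convergence rule** — a running statistic (either of the
   above, tracked as conformations accrue) is declared converged at
   sample size *n\** once the changes produced by the next `window`
   additions (default 5) all stay below `threshold` (default 5%).  The
   combined criterion takes the later of the two counts.

4. **Hierarchical screening protocol** — pre-screen every conformation
   with a small QM region (cheap), rank barriers lowest→highest, then
   evaluate the big QM region (expensive) in that order until both
   criteria converge.  Cost is accounted in big-QM-evaluation
   equivalents; with small-QM work at 10% relative cost, stopping after
   8 of 20 conformations saves 50% of the no-screening bill.

A seeded synthetic generator (correlated bivariate small/big barriers on
an MD time grid, positivity-enforced) makes every part testable without
QM/MM data, and a delimited-table/JSON I/O layer plus CLI ties the
pipeline together.

## Worked example

Using the bundled synthetic demonstration table (20 snapshots at 0.5 ns;
`facd_like_synthetic_paired.tsv` is generated data, not measured
barriers):

```r
library(qmmconverge)
path <- system.file("extdata", "facd_like_synthetic_paired.tsv",
                    package = "qmmconverge")
p     <- read_barriers(path)            # paired small/big QM table
small <- ensemble_side(p, "small")

boltzmann_average(small)        # 16.47 kcal/mol
arithmetic_average(small)       # 21.68 kcal/mol  (Jensen: always higher)
disproportionate_effect(small)  # 17.5 %
combined_converged_after(small) # 7 conformations
barrier_correlation(p)          # 0.56 small/big rank correlation

run_protocol(p, cost = cost_model(0.1))
#> Screening protocol over 20 conformation pairs
#>   big-QM evaluations: 9 (converged, rule fired at n = 4)
#>   Boltzmann-weighted average: 8.614 kcal/mol
#>   disproportionate effect: 35.88 %
#>   total cost: 11 big-QM equivalents; savings 45% of baseline 20
```

Reading: the exponential average (16.47) sits far below the arithmetic
mean (21.68) because the lowest barriers dominate; the 5%-over-5 rule is
satisfied after 7 snapshots for this series; and ranked screening needed
only 9 of 20 expensive evaluations — 20 cheap + 9 expensive = 11 big-QM
equivalents, 45% below the 20-evaluation baseline.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/qmmconverge.R simulate --seed 42 --out pairs.tsv
Rscript inst/cli/qmmconverge.R protocol --input pairs.tsv --relative-cost 0.1
Rscript inst/cli/qmmconverge.R converge --input pairs.tsv --threshold 5 --window 5
```

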