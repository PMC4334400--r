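# assaychoice

Decision support for choosing genetic assays in rare-disease
gene-discovery studies. Budgets, not case availability, usually limit
such studies, so the central question is whether to assay a few cases
deeply (whole-genome or whole-exome sequencing) or many cases shallowly
(CNV genotyping chips) — and, for an existing study, whether to add
subjects or to re-assay the ones you have.

## The model

Each case carries a private causal mechanism of `c` risk mutations (the
disease *complexity*), with no overlap across cases. An assay with hit
rate `v` covers each mutation independently, so a case's complete
mechanism is observed with probability `d = v^c`, and across `n`
case-units (singletons or trios — whatever the price quotes) the number
of completely observed mechanisms is `m ~ Bin(n, v^c)` with mean
`E[m] = n v^c`. The cost-effectiveness of an assay priced `P` per
case-unit is

```
U = E[m] / (n P) = v^c / P
```

independent of `n`, which makes assay ranking budget-free. For extending
an existing study at equal cost, adding subjects (strategy A) ties with
re-assaying existing subjects (strategy B) exactly on the boundary
`v_B / v = (P_B / P_A + 1)^(1/c)`, from which the package derives the
minimum hit-rate increment a second assay must confer, the base hit rate
at which more subjects would be just as good, and a full partition of the
price-ratio / hit-rate-ratio plane by favoured strategy. A Monte-Carlo
simulator of the generative model provides an independent check on every
closed form.

## Worked example

Four exome-sequenced trios versus sixteen chip-genotyped trios on the
same budget, at complexity 2:

```r
library(assaychoice)
catalog <- list(assay("WES", hit_rate = 0.27, price = 4),
                assay("chip-CNV", hit_rate = 0.12, price = 1))
rank_assays(budget = 16, catalog, disease_model(2))
#> Assay ranking at budget 16, complexity c = 2
#>
#>     assay hit_rate price  n discoverability expected_yield utility budget_left
#>       WES     0.27     4  4          0.0729           0.29 0.01823           0
#>  chip-CNV     0.12     1 16          0.0144           0.23 0.01440           0
#>
#> WES yields 26% more expected mechanisms than chip-CNV (0.29/0.23 = 1.26; full precision 1.266)
```

Exome sequencing wins: 0.29 expected completely observed mechanisms
versus 0.23, despite assaying a quarter as many trios. Extending that
study — a fifth exome trio, or chip-genotyping the existing four at the
same total cost:

```r
sc <- extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
                         complexity = 2, extra_hit_rate = 0.12)
extension_yields(sc)
#> Study extension verdict
#>   strategy A (n 4 -> 5 at v = 0.27): E[m_A] = 0.365 (0.3645)
#>   strategy B (v 0.27 -> 0.39 at n = 4): E[m_B] = 0.608 (0.6084)
#>   favoured: B
#>   breakeven: strategy B must add at least 0.0319 to the hit rate
#>   breakeven: strategy A ties only if the base hit rate were 1.02 (infeasible: exceeds 1)
```

Re-assaying wins decisively: the chip only needs to add 0.032 to the hit
rate to break even, while more subjects could only tie if exome
sequencing had an impossible hit rate of 1.02.
`partition_parameter_space()` maps this comparison over the whole
price-ratio / hit-rate-ratio plane (and `plot()` draws it);
`simulate_study()` / `simulate_extension()` verify any of these numbers
by simulation.

A command-line wrapper with `design`, `extend`, `partition` and
`simulate` subcommands is installed at
`system.file("cli", "assaychoice.R", package = "assaychoice")`, and a
default assay catalog (chip-CNV 0.12, WES 0.27, WGS 0.62 — lower-bound
hit rates) ships in `inst/extdata/`. See the vignette
(`vignettes/assay-choice.Rmd`) for the model's assumptions and the
package's numerical conventions.

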