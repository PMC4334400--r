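---
title: "Choosing genetic assays cost-effectively in rare-disease studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing genetic assays cost-effectively in rare-disease studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assaychoice)
```

## The problem

Rare-disease gene discovery is usually limited by assay cost, not by case
availability. Whole-genome sequencing, whole-exome sequencing and CNV
genotyping chips differ enormously in both price and in the fraction of
disease-relevant variation they can see, so the designer of a study on a
fixed budget faces a real trade-off: assay a few cases deeply, or many
cases shallowly? `assaychoice` makes that trade-off explicit and
computable.

## The model

Each case of a rare oligogenic disease is assumed to carry a private
*causal mechanism*: a set of `c` risk mutations (the *complexity*), none
sufficient alone, that jointly cause the disease. Mechanisms are assumed
not to overlap across cases. An assay covers any given risk mutation with
probability `v`, its *hit rate*, independently across mutations. A case's
mechanism is completely observed — the prerequisite for it ever being
identified — only when all `c` of its mutations are captured, which
happens with per-case *discoverability*

$$ d = v^c. $$

Across `n` assayed case-units the number `m` of completely observed
mechanisms is binomial, $m \sim \mathrm{Bin}(n, d)$, with expectation

$$ E[m] = n\,v^c. $$

A *case-unit* is whatever unit the price quotes: a singleton case or a
parent-offspring trio; the model never assumes family structure. The
cost-effectiveness (*utility*) of an assay priced at `P` per case-unit is
the expected number of completely observed mechanisms per currency unit,

$$ U = \frac{E[m]}{nP} = \frac{v^c}{P}, $$

which is independent of `n`, so it ranks assays for any budget. Setting two
utilities equal gives the price multiple at which a better assay is still
worth it: $P_2 / P_1 = (v_2 / v_1)^c$. High complexity favours deep
assays dramatically — at `c = 2`, twice the hit rate justifies four times
the price.

Treating `d = v^c` as exact assumes every case carries exactly `c` causal
mutations. Cases carrying more are harder to observe completely, but for
rare diseases they are a negligible fraction; the simulator's `prop_extra`
option lets you probe the size and direction of that bias (it can only
lower discovery).

## Scenario 1: designing a new study

`rank_assays(budget, catalog, disease)` evaluates every assay at the
budget: the affordable sample size is `floor(budget / P)` (whole case-units
only — worked examples in the field use exactly divisible budgets, and
flooring is the conservative generalisation; leftover budget is reported),
then `E[m]` and `U` follow from the closed forms.

```{r}
catalog <- list(assay("WES", hit_rate = 0.27, price = 4),
                assay("chip-CNV", hit_rate = 0.12, price = 1))
rank_assays(budget = 16, catalog, disease_model(complexity = 2))
```

Two reporting conventions coexist deliberately. Full-precision yields are
always carried (0.2916 and 0.2304 above), but practitioners quote 2-dp
figures, and the familiar headline comparison — "26% better,
0.29/0.23 = 1.26" — is only reproducible from the rounded intermediates
(the full-precision ratio is 1.266). The ranking object therefore carries
both, and display rounding uses round-half-away-from-zero so printed
figures never surprise anyone with round-half-to-even.

Ties in utility are broken by lower price, then name, so output is
deterministic. Because integer `n` can leave different amounts of budget
unspent under different assays, ranking by realised yield `n v^c` can
disagree with the scale-free utility ranking; the object flags any
disagreement rather than hiding it.

## Scenario 2: extending an existing study

Given an existing study (`n` case-units at hit rate `v`) and an extension
budget, two strategies compete:

* **A** — assay new case-units with the original assay, raising `n` to
  `n_A`;
* **B** — run an additional assay on the existing case-units, raising `v`
  to `v_B`.

Their yields are $E[m_A] = n_A v^c$ and $E[m_B] = n\,v_B^c$. When the two
assays cover disjoint mutation classes (say, exome point mutations and
chip-detected CNVs), hit rates add: `v_B = v + Δ`. The package generalises
this minimally with a single scalar `overlap` subtracted from the sum,
defaulting to zero; no finer model of shared coverage is attempted, because
none is identifiable from the quantities users actually have.

```{r}
sc <- extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
                         complexity = 2, extra_hit_rate = 0.12)
extension_yields(sc)
```

Under the equal-budget constraint $(n_A - n) P_A = n P_B$, combining the
constraint with the yield-equality condition $n_A / n = (v_B / v)^c$ gives
the breakeven locus

$$ \frac{v_B}{v} = \left(\frac{P_B}{P_A} + 1\right)^{1/c}, $$

independent of sample size. Rearrangements give the minimum increment
`min_extra_hit_rate()` that strategy B must confer, and its inverse
`required_base_hit_rate()`; results above 1 are returned with an
`infeasible` attribute rather than an error, since "no real assay could
achieve this" is itself the informative answer.

`partition_parameter_space()` maps the whole plane of price ratio
$P_B/P_A$ versus hit-rate ratio $v_B/v$, labelling each grid cell A, B,
`equivalent`, or `infeasible` (an additional assay cannot lower coverage,
so $v_B/v < 1$ is excluded). The axes are ratios, so the picture is
scale-free. `plot()` shades the plane and overlays the equivalence curves:

```{r, fig.width = 6, fig.height = 4.5}
pg <- partition_parameter_space(c(0.05, 2), c(0.95, 2),
                                complexities = c(1, 2, 4, Inf),
                                resolution = 81)
plot(pg)
```

## Parameters that matter

* **`complexity` (c)** — risk mutations per mechanism; dimensionless,
  typically an integer, default nowhere (it must be chosen). Any real
  `c >= 1` is accepted: the closed forms are well defined for real
  exponents and decision boundaries are usefully swept continuously;
  `Inf` is handled analytically (the boundary becomes the constant line
  `v_B/v = 1`), never by large-`c` numerics. Power collapses rapidly with
  `c`, so a low working value such as 2 is the pragmatic choice.
* **`hit_rate` (v)** — probability in [0, 1] a risk mutation is covered.
  The bundled catalog ships chip-CNV 0.12, WES 0.27, WGS 0.62; these are
  diagnostic rates for severe intellectual disability, a disease of
  complexity about 1, so they are lower bounds and should be replaced with
  disease-specific estimates when available.
* **`price` (P)** — per case-unit, any positive currency; every decision
  quantity depends on price ratios alone. The bundled prices are
  chip-units: WES 4, WGS 16.

## Numerical choices

* Equal-budget arithmetic supports two conventions: continuous
  `n_A = n + budget / P_A`, which the breakeven algebra assumes and the
  property checks use, and whole case-units via `floor`, used for concrete
  advice (`continuous_n = FALSE`, the default).
* Yield comparisons classify as `equivalent` within a relative tolerance
  of 1e-9, so grid cells sitting numerically on a boundary cannot
  oscillate between labels.
* A strategy whose cost exceeds the budget is flagged in
  `feasibility_notes`, and the verdict degrades to `"A"` or
  `"infeasible"` rather than erroring: partial answers are still answers.
* Degenerate boundaries (a free additional assay, or infinite complexity)
  make `required_base_hit_rate()` ill-defined; it stops with an
  explanation instead of returning 0/0.

## The simulator

`simulate_study()` draws the generative model directly — per case,
`c` independent capture events with probability `v`, the case counting
only if all succeed — and therefore shares no code path with `v^c`. Its
empirical mean, variance, and full count distribution are checked against
the closed forms in the test suite (mean within 3 standard errors, and a
chi-square goodness-of-fit of the counts against the binomial masses).
The default 100,000 replicates resolve example-scale differences in
seconds; tests use between 10,000 and 100,000 depending on how sharp the
comparison needs to be. `simulate_extension()` runs both strategies from
one seeded stream and summarises the paired yield difference.

What the simulator emulates is exactly the model's assumptions — no
mutation identities, genomic positions, assay errors, or candidate-
mechanism false positives. Agreement between simulation and closed form
therefore validates the algebra and the implementation, not the model's
fidelity to real data.

## Limitations

The framework maximises the number of completely observed mechanisms; it
says nothing about distinguishing true mechanisms from the many plausible
candidates an assay generates per case, about assay error rates or
validation costs, or about the sequential-analysis issues raised by
re-analysing an augmented dataset. Hit rates and complexity are inputs,
not estimates, and conclusions can be sensitive to them — though the
worked extension example shows the verdict is often robust across a wide
parameter range. All results are exportable via `render_report()` /
`write_report()` as TSV, JSON (full precision) or text.
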