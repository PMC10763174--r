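# randelphi

Consensus analysis for multi-round RAND/UCLA appropriateness panels.

Expert panels rating clinical scenarios — for example, opioid
prescribing-safety indicators in primary care — score each scenario from 1
(highly inappropriate) to 9 (highly appropriate) over two or more Delphi
rounds with anonymised feedback in between. `randelphi` implements the
quantitative machinery such studies use, for analysts who have panel
ratings (or only the published summary tables) and want the statistics,
classifications and round-to-round bookkeeping reproducibly:

* **Consensus statistics** per item: median, 30th/70th percentiles, the
  interpercentile range `IPR = P70 − P30`, its symmetry-adjusted
  counterpart `IPRAS = 2.35 + 1.5·|5 − (P30 + P70)/2|`, and the
  **disagreement index** `DI = IPR / IPRAS`.
* **Classification**: `DI < 1` is agreement; the median then places the
  item in the *inappropriate* (1–3), *equivocal* (4–6) or *appropriate*
  (7–9) band — labels `A/IA`, `Neutral`, `A/A`, or `Disagreement`.
* **Multi-round linkage**: item lineage (identical / modified / split),
  band-transition tables, convergence flags, and per-category cross-tabs
  of agreed-inappropriate items.
* **Reporting** in the field's customary table shapes (CSV/TSV/Markdown).
* A **seeded synthetic panel generator** (consensus, polarized and
  uniform item archetypes; attrition; feedback shift) plus
  `recovery_experiment()` for the operating characteristics of the
  consensus criteria.
* Bundled example data: the published round summaries of a two-round
  e-Delphi study in which 24 (then 19) UK experts rated 20 opioid
  prescribing scenarios, plus 13 reworded/split items in round 2.

## Worked example

Summarise one item's panel and classify it:

```r
library(randelphi)
ratings <- c(1, 1, 2, 2, 2, 2, 3, 3, 5)
s <- summarize_item(ratings)
s
#>  n median p_low p_high ipr iprcp  ai ipras      di n_low n_mid n_high
#>  9      2     2    2.6 0.6   2.3 2.7   6.4 0.09375     8     1      0
classify(s$median, s$di)
#>  agreement          band label
#>  agreement inappropriate  A/IA
```

Nine panellists with median 2: the 30th/70th percentiles are 2 and 2.6,
so the spread (IPR 0.6) is far below the asymmetry-adjusted bound
(IPRAS 6.4), giving DI ≈ 0.094 — strong agreement — and the median's
band makes the verdict "agreement on inappropriateness" (`A/IA`).

Classify the bundled published summaries and tabulate verdicts per round
(20 original scenarios; round 2 recovers the study's 15 inappropriate /
5 equivocal split):

```r
published <- opioid_delphi_summaries()
cl <- classify_summaries(published)
originals <- cl[!cl$item_id %in% opioid_delphi_lineage()$child_id, ]
table(round = originals$round, verdict = originals$label)
#>      verdict
#> round A/IA Neutral
#>     1   12       8
#>     2   15       5
```

(The round-1 recount is 12/8 against the study's printed 13/7: one
printed row labels a median-4 item agreed-inappropriate, an
inconsistency in the source table that recomputation surfaces.)

`transition_table(cl, opioid_delphi_lineage())` then reports which items
converged from agreed-equivocal to agreed-inappropriate — between rounds
for unchanged items, and relative to the parent item for reworded ones —
and `category_crosstab()` counts agreed-inappropriate items per
prescribing-problem category.

A command-line wrapper is installed at `exec/randelphi` with
`summarize`, `compare` and `simulate` subcommands over the same
functions.

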