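# drugsynergy

Quantitative toolkit for two-drug combination studies in cell-based
models, with seeded synthetic-data generators so every stage is testable
end-to-end without external data.

When two drugs are combined — for example an MDM2 inhibitor that
stabilizes p53 together with a BET inhibitor that displaces BRD4 from
chromatin — the central question is whether the combination does more
than the sum of its parts, and through what downstream machinery. This
package implements the standard quantitative answers at each layer:

- **Dose-response synergy** (`fit_median_effect`, `combination_index`):
  Chou–Talalay median-effect fitting of each agent and of a
  constant-ratio combination series, and the Loewe-based combination
  index CI = D1/Dx1 + D2/Dx2 at experimental doses and ED50/75/90.
  CI < 1 means synergy.
- **Plate-level synergy** (`normalize_viability`, `cdi`,
  `excess_over_bliss`): the coefficient of drug interaction
  CDI = AB/(A×B) on surviving fractions with a replicate-level Welch
  test, and excess-over-Bliss scoring of full dose checkerboards.
- **Synergy genes** (`call_synergy_genes`, `intersect_gene_set`,
  `p53_dependence`): the C/(A+B) ≥ 1.25 rule on four-condition
  expression tables, hypergeometric overlap with curated gene sets, and
  a knockdown-dependence contrast.
- **mRNA stability** (`relative_abundance`, `fit_decay_table`,
  `compare_stability`): delta-Ct half-life estimation from
  transcription-shutoff qPCR timecourses.
- **ChIP peaks** (`consensus_peaks`, `annotate_peaks`,
  `gene_binding_matrix`): replicate-consensus intervals at k-of-n
  support, genome occupancy, promoter annotation and gene-level binding
  matrices, on BED-convention coordinates via GenomicRanges.
- **Simulation** (`gen_*`): seeded generators for every input type with
  recorded ground truth (Loewe/Bliss/potency-synergy truths, planted
  synergy genes, planted peaks).

## Worked example

```r
library(drugsynergy)

# a simulated constant-ratio experiment with true 2x potency synergy
g <- gen_dose_response(seed = 7, model = "potency_synergy", alpha = 2,
                       noise_sd = 0.02)
combination_index(g$design)
#> <ci_profile>
#>   summary CI: ED50 = 0.490, ED75 = 0.493, ED90 = 0.495

# a viability plate with a strongly synergistic combination
p <- gen_viability_plate(seed = 7, A = 0.6, B = 0.5, AB = 0.1,
                         noise_sd = 0.05)
cdi(normalize_viability(p$plate))
#> <cdi_result> CDI = 0.3554 (synergistic), p = 0.00382 [n_combo = 3, n_products = 3]

# synergy-gene calling on a planted expression table
e <- gen_expression_matrix(seed = 7, n_genes = 1000, n_up = 40,
                           n_down = 15, noise_sd = 0.1)
rec <- call_synergy_genes(summarize_conditions(e$expr, e$sheet))
table(rec$class)
#> down none   up
#>   15  943   42
```

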