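# crmpair

Discriminative mining of tissue-specific **cis-regulatory modules (CRMs)**
from the vicinity of related genes, for regulatory genomicists who have a
gene set and a motif library but no validated enhancers to train on.

A CRM is a non-coding segment where binding sites of several transcription
factors cluster. `crmpair` assumes the CRMs of co-regulated genes share
co-occurring **motif pairs**, and finds them by contrasting a *mixed* set
(sequences near the genes, e.g. conserved non-coding elements) against
length-matched genomic *controls*:

* a motif pair occurring n_m times in the mixed set and n_c times in the
  controls (total lengths l_m, l_c) is enriched by
  **E-value_p = (l_c / l_m) · (n_m / n_c)**; pairs must pass a minimum
  occurrence count, E-value_p > 1, and an outlier band (strictly between
  the mean enrichment and `cap_sd` standard deviations above it);
* a greedy algorithm co-selects the **regulatory signature** (ordered pair
  list) and a candidate sequence set maximising the set enrichment
  **E-value_h = (l_c / l_m) · (r_m / r_c)**, stopping before any step that
  would drop E-value_h below a floor or overflow the candidate cap;
* candidates are scored by 0–1 weighting (each signature pair present
  within the distance constraint contributes its E-value_p once) and an
  empirical Bayesian threshold t maximising
  log p(mixed | T ≥ t) − log p(control | T ≥ t) separates putative CRMs
  from background;
* the six tunable parameters are optimised on a 50/25/25 locus split with
  Bonferroni-corrected one-tailed Fisher tests at training/validation and
  a single blind evaluation of the selected model on the test fold.

Motif hits come from the built-in log-odds PWM scanner (MEME-minimal
input, exact p-value-to-score conversion) or any external scanner via a
TSV hit table. A synthetic benchmark generator plants motif-pair
signatures in background sequences at configurable noise folds, with
ground truth, for end-to-end validation.

## Worked example

```r
library(crmpair)

# 40 loci, 3 CRMs per locus each carrying two planted signature pairs,
# training/validation folds diluted with 10 background sequences per locus,
# controls at 1:5
bench <- generate_benchmark(sim_config(seed = 1, x = 10))
res   <- run_benchmark(bench, grid = desk_grid())
res$mine
#> Parameter combinations run: 8 (Bonferroni threshold 0.00625)
#> Passing train+validation: 8
#> Best combo: 3 (max_gap=50, min_occ=7, cap_sd=4.0, min_Eh=3, k=1, max_cand=160)
#> Test: E-value_h = 23.18, p = 1.9e-18 -> SUCCESS; 28 putative CRMs
str(res$truth_eval)
#> List of 6
#>  $ tp             : int 25
#>  $ n_predictions  : int 28
#>  $ precision      : num 0.893
#>  $ no_skill       : num 0.333
#>  $ recovered_pairs: num 0.8
#>  $ n_planted_pairs: int 5
```

Reading the output: all 8 parameter combinations found a significantly
enriched prediction set on both training and validation folds; the
selected model predicted 28 CRMs in the blind test fold, 23-fold more
enriched with mixed-set sequences than with controls (Fisher p = 1.9e-18,
well under the 0.05 test threshold). Against the planted ground truth, 25
of the 28 predictions are true CRMs (precision 0.89 vs the 0.33 no-skill
rate) and 4 of the 5 planted signature pairs were recovered in the mined
signature. On signature-free input (`make_null()`) the same pipeline
returns a failure verdict.

A command-line wrapper for FASTA/MEME/TSV inputs is installed at
`inst/scripts/crmpair-run.R`; the methods vignette
(`vignettes/motif-pair-mining.Rmd`) documents the model, parameter
defaults, and numerical conventions.

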