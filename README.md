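# brafpocket

Why does one activating kinase mutation dominate the somatic cancer
catalogue while energetically similar ones stay rare? In BRAF, V600E — a
charged substitution buried in the hydrophobic pocket that locks the
activation segment (AS) in its inactive conformation — accounts for the
overwhelming majority of catalogued kinase-domain mutations, yet V600K,
V600D or L597E should release the segment just as well. `brafpocket`
implements the structure-energy statistical pipeline that dissects this
pattern, and a synthetic-data generator with known ground truth so the whole
pipeline can be validated end to end without external downloads.

## The model

For every substitution *m* at a pocket position, the pipeline assembles
seven predictors of its catalogued frequency:

1. **ΔΔG<sub>inactive</sub>** — mean folding-energy change over
   inactive-state structure templates (kcal/mol; > 0.8 kcal/mol counts as
   destabilizing, a strict threshold equal to twice the force-field error).
2. **ΔΔG<sub>active</sub>** — the same over active-state templates.
3. **ΔΔG<sub>loop</sub> · p(i)** — the inactive AS-loop destabilization,
   scaled by the presence fraction *p(i)*: the proportion of ensemble
   crystal structures that resolve residue *i*. Flexible (often-unsolved)
   positions tolerate destabilization without unfolding.
4. **n<sub>sub</sub>** — the minimum number of nucleotide substitutions
   turning the reference codon into one encoding the mutant amino acid
   (V600E needs one base change, V600K/D two, V600H three).
5. **Δusage** — change in codon-usage fraction (mutant − wild-type codon).
6. **E<sub>salt</sub>** — a favorable phosphomimetic salt-bridge energy for
   Asp/Glu at Thr599/Lys601/Ser602 (never position 600, whose side chain
   points away from Arg575 in the active state).
7. **ΔΔG<sub>solvH</sub>** — the change in hydrophobic (apolar) solvation
   energy.

A composite activation score ranks mutations that open the segment without
wrecking the active fold:

```
score = ΔΔG_loop·p  −  (ΔΔG_active + E_salt)  +  ΔΔG_solvH
```

The contribution of each predictor to the observed frequencies (response:
log10(count + 1)) is quantified by a balanced random-forest regression
protocol: two sets of 100 runs, each training on ~70% of the mutations
sampled separately from the zero-count and nonzero-count strata, with the
hotspot mutation forced into (set 1) or out of (set 2) the training set;
40 trees, 4 candidate variables per split; per-run performance =
Pearson correlation / RMSD on the held-out 30%; feature importance =
total node-impurity (RSS) decrease, averaged per set and normalized to
percent.

## Worked example

```r
library(brafpocket)

sim <- simulate_pocket_study(synthetic_config(seed = 42))
head(sim$features[order(-sim$features$count),
                  c("mutation", "f3_loop_destab", "f4_nt_substitutions", "count")])
#>  mutation f3_loop_destab f4_nt_substitutions count
#>     L597R       3.217365                   1  2195
#>     A598D       2.350935                   1   347
#>     L597Q       1.916910                   1   146
#>     V600E       1.822170                   1   125
#>     A598H       2.847330                   2   113
#>     A598G       1.987380                   1   106

prot <- run_protocol(sim$features, forest_config(), seed = 42)
prot
#> Balanced random-forest importance protocol
#>   100 runs per set, 40 trees, mtry 4, train fraction 0.70
#>   hotspot: V600E
#>
#> Mean feature importance (% of total node-impurity decrease):
#>                 f1_inactive_destab f2_active_destab f3_loop_destab
#> with_hotspot                  13.4              7.6           54.4
#> without_hotspot               13.4              6.8           55.0
#>                 f4_nt_substitutions f5_usage_delta f6_saltbridge f7_solvh_delta
#> with_hotspot                   14.1            3.7             0            6.8
#> without_hotspot                14.3            4.0             0            6.4
```

The synthetic cohort reproduces the hallmark pattern: the most frequent
mutation (here L597R) is a single-base charged substitution with the
highest flexibility-corrected loop energy — the V600E profile — and the
corrected loop-destabilization feature dominates the forest importances in
both protocol sets, with the accessibility and folding features as
secondary contributors. Each column of `sim$features` can be traced back to
the generating configuration (`sim$config$true_feature_weights`), which is
what makes the recovery checks in `tests/testthat/` possible.

Individual stages are exposed directly: `min_nt_substitutions("GTG", "E")`
returns `1`; `presence_profile(read_ensemble_residues(files, 597:615))`
computes resolved fractions and normalized B-factors from PDB files;
`summarize_energies()` applies the threshold, flexibility and salt-bridge
corrections and the activation score to any ddG table read with
`read_ddg_table()`.

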