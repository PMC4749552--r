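---
title: "Dissecting hotspot mutation frequencies in the BRAF hydrophobic pocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hotspot mutation frequencies in the BRAF hydrophobic pocket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brafpocket)
```

## The scientific problem

The BRAF kinase is held inactive by hydrophobic interactions between its
activation segment (AS) and the N-terminal lobe: Val600 sits buried in a
pocket formed by Phe468, Leu485, Val487, Ala497, Phe498 and Leu525 of the
N-lobe and Leu597, Ala598 and Trp604 of the segment itself. Charged
substitutions at position 600 disrupt the pocket, release the segment and
activate the kinase constitutively — yet among all pocket substitutions
that should do this, only V600E dominates the somatic cancer catalogue.

The pipeline in this package formalizes the explanation as a balance of
four forces: (i) how much a substitution destabilizes the autoinhibitory
loop conformation (activation), (ii) how much it destabilizes the folded
inactive and active states (loss of protein), (iii) how many nucleotide
substitutions the change requires (mutational accessibility), and (iv)
codon-level effects on expression. Each force becomes a quantitative
feature; a regression-forest protocol then apportions their contributions
to the observed frequencies.

## Pipeline stages and their assumptions

### Codon accessibility

`min_nt_substitutions()` is the Hamming distance from the reference codon
to the nearest codon of the target amino acid under the standard genetic
code. The reference codons for the 14 pocket positions
(`braf_pocket_reference()`) are pinned where printed substitution distances
force them (Val600 = GTG, Leu597 = CTG) and otherwise chosen as common
human codons consistent with every published distance; they are plain
data and can be replaced. `usage_delta()` scores the codon-usage change;
when several mutant codons tie at the minimal distance, the one with
maximal usage is selected (the most accessible high-expression outcome),
with an alphabetical tie-break for determinism. The "nucleotide
substitution" feature is the *count* of required bases, not a
signature-weighted rate: transition/transversion and trinucleotide-context
weighting are deliberately out of scope, and an alternative
frequency-weighted definition could be slotted in behind the same
interface.

### Ensemble flexibility

"Resolved" means the residue has an alpha-carbon record in the chosen
chain — side-chain completeness is not required, matching the crystallographic
notion of a solved position. One chain is counted per structure (the first
covering the residue range, or an explicit chain map), so crystals with
several copies in the asymmetric unit do not dominate the statistics.
B-factors are z-normalized *within* each structure over the analysed range
(population SD), because absolute temperature factors are not comparable
across crystals; "normalized B-factor" in reports means exactly this
dialect. A structure with constant B-factors carries no spread information
and contributes zeros (with a warning); author residue numbering is taken
verbatim.

### Energy corrections and the activation score

Folding-energy changes come from per-mutation ddG tables computed on
active- and inactive-state template structures; this package consumes such
tables (`read_ddg_table()`) and never recomputes force-field energies.
Means are taken per state; a mean above the strict 0.8 kcal/mol threshold
(twice the force-field error) is destabilizing. The inactive loop energy of
mutations at segment positions 597–615 is multiplied by the residue's
presence fraction — the minimal monotone reading of "corrected by the
frequency at which the position is solved"; the form is a config point
(`energy_config()`), and the correction is never applied to active-state
energies, whose templates resolve the loop only to position 600 without
destabilization. When tables carry a loop-restricted `ddg_loop` column it
is used directly; otherwise the whole-protein ddG stands in for loop
mutations and 0 for others, a documented fallback dialect.

Phosphomimetic Asp/Glu at Thr599, Lys601 or Ser602 can form the activating
salt bridge with Arg575 and receive a favorable configured energy,
`saltbridge_value`. The value itself is a required configuration parameter
for reproduction runs: it was originally calibrated from a
phospho-Ser → Ser calculation on the cAMP-dependent protein kinase (PDB
1ATP) but never published; the default −2.0 kcal/mol is an explicit
placeholder of plausible phosphomimetic magnitude. Position 600 never
qualifies, and the potential Glu600–Lys507 salt bridge is fixed at zero
energy (both side chains are solvent-exposed and unconstrained; the
corresponding alanine-revertant energy is 0.04 ± 0.1 kcal/mol).

The composite score,
`loop_corrected − (mean_active + saltbridge) + solvh_inactive`, uses the
raw apolar solvation term as the hydrophobicity factor. An alternative
sign-adjusted "bulky-hydrophobic accommodation" penalty was considered and
not adopted: the raw term already separates charged from hydrophobic
substitutions and keeps the score a sum of force-field quantities.

### Feature matrix and response

`build_feature_matrix()` inner-joins energies, accessibility and counts on
the mutation key, warns about drops, and orders rows deterministically
(position, then mutant amino acid). The response is `log10(count + 1)` by
default: catalogue counts span 1 to >20,000, and a raw-count response
would let the single dominant hotspot own the entire residual sum of
squares. Zero-count mutations are retained — they form the low-frequency
stratum used for balancing.

### The forest protocol

Each run draws `floor(0.7 · n)` training mutations independently from the
zero-count and nonzero-count strata (the balancing boundary is
configurable), fits a 40-tree regression forest with 4 candidate variables
per split (bootstrap resampling within trees, the standard for this
estimator), and evaluates Pearson correlation, RMSD and their ratio on the
held-out mutations. Importance is the total RSS node-impurity decrease —
*not* permutation importance — summed over all splits per feature and
averaged over the 100 runs of each set, then normalized to percent. The
two sets differ only in whether the hotspot mutation is forced into or
kept out of every training set; a forest cannot extrapolate beyond its
training range, so this probes whether the dominant observation drives the
conclusions. No run filtering precedes the importance averaging: every run
counts, and the per-run performance table is returned so a user can study
the dependence themselves. Degenerate cases are defined, not hidden: a
constant training response gives a zero-importance fit with a warning, an
exactly-zero test RMSD flags infinite performance, and constant
predictions leave the correlation undefined (an error).

## The synthetic-data generator

`simulate_pocket_study()` generates every pipeline input under one master
seed with known ground truth. What it emulates, and what it does not:

* **Energy tables.** Each mutation gets latent loop, inactive-folding and
  active-folding energies from a mutation-type model: charged substitutions
  in the pocket are strongly destabilizing (~2.8 kcal/mol), small polar
  ones intermediate, bulky hydrophobics mildly so (the flexible segment
  accommodates them), identity substitutions exactly zero. Folding terms
  scale with local rigidity (N-lobe rigid, segment flexible), and
  active-state energies carry only a weak echo of the pocket effect plus
  state-specific noise — the construction that makes same-state template
  pairs correlate near the configured 0.8 and cross-state pairs far lower.
  Template replicates add noise scaled as `sd(latent)·sqrt((1−ρ)/ρ)` so
  the within-state correlation hits its target. Energies are rounded to
  4 decimals so written tables round-trip exactly.
* **Structure ensembles.** Alpha-carbon-only PDB files in which each loop
  residue appears independently with its configured presence fraction
  (0.70 at residue 600; an ordered start, a disordered mid-loop) and
  B-factors rise as presence falls. These are *minimal* synthetic
  crystals: no side chains, no occupancies, no alternate locations.
* **Counts.** Poisson with a log-linear link on the standardized features,
  `λ = exp(α + Σ wᵢ zᵢ) · g^max(f4−1, 0)`. The default weights put the
  dominant effect on the corrected loop energy (w₃ = 1.5), moderate
  effects on active-state folding, codon usage and solvation, and
  near-zero on features 1 and 6 — the contribution pattern the protocol
  should recover. The accessibility gate g = 0.1 makes each base beyond
  the first an order of magnitude of rarity, the separation observed
  between the one-base and two-base substitutions at position 600 in the
  somatic catalogue; the exponent is clamped at zero so identity
  substitutions (0 bases) are not amplified. Features are standardized
  before the link so the weights are comparable in magnitude.

Passing the recovery tests on this generator shows that the pipeline's
statistics behave as designed under a known truth — it does **not** show
that real folding energies follow the mutation-type model, that real
counts are Poisson, or that real feature correlations match the synthetic
ones. Real catalogue counts are overdispersed, tissue-confounded and
subject to sequencing-panel ascertainment, none of which the generator
models.

## Problem sizes and numerical choices

The test-suite and acceptance computations run at the study's own scale:
280 mutations × 5 templates (1400 models), 100 forest runs per set, and
20 protocol repetitions for the recovery rate; the synthetic ensemble for
the presence check uses 1000 structures so the binomial standard error
(≈0.014) cleanly separates 0.70 from its neighbours. All randomness flows
from explicit seeds; the protocol result is bit-reproducible from its
master seed. Ties in codon selection break by usage then alphabetically;
ties at forest splits are handled inside the forest implementation under
the same seed discipline.

## Known limitations

* The salt-bridge energy is a placeholder until calibrated against a
  phosphomimetic reference computation; conclusions about feature 6 should
  not be read off the default.
* The loop-energy fallback (whole-protein ddG for segment mutations)
  overstates feature 3 for mutations that destabilize both the loop and
  the core; supplying a `ddg_loop` decomposition avoids this.
* Presence fractions count one chain per structure; ensembles in which
  chain copies differ substantially in loop order need an explicit chain
  map, and occupancy-weighted presence is not implemented.
* The importance protocol quantifies association under the forest model,
  not causality; correlated features (1 and 3 here, by construction and
  in reality) share importance in proportions that depend on `mtry`.
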