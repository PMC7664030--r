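---
title: "Methods: explainable kinase-inhibitor response modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable kinase-inhibitor response modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmart)
```

## The modeling problem

Drug response screens report a log-scale IC50 for each drug x cell-line
pair. `qsmart` regresses log-IC50 on features that a pharmacologist can
read: drug substructure fingerprint bits, multi-omics cell-line features
at seven levels of biological organization, and product-interaction
terms that are admitted only after passing an individual statistical
test. A compact neural network then captures residual non-linearity on
the few dozen selected features. This vignette records the model, the
tunable parameters, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Feature construction

**Residue level.** Mutations are projected onto the reference protein
kinase A (PKA) numbering so that equivalent structural positions line up
across kinases (EGFR L858R maps to PKA position 187). For each mutated
position a cell line gets eight columns, `PKA_<pos>_<PROP>`: a mutation
count (`MUT`), six mutant-minus-wild-type physicochemical deltas
(`CHA` charge in unit charges, `POL` binary polarity class, `HYD`
Kyte-Doolittle hydrophobicity, `ASA` accessible surface area in
square Angstroms, `VOL` side-chain volume in cubic Angstroms, `ENE`
octanol transfer free energy in kcal/mol), and the BLOSUM62
substitution score (`BLO`, from Biostrings). Deltas from several
mutations at one position are summed rather than averaged, which keeps
them additive with the count column; swapping wild type and mutant
negates every delta. Polarity is coded polar = 1 / nonpolar = 0 so its
delta lies in {-1, 0, 1}. The property table ships in code and every
column can be overridden (`aa_properties(override = ...)`): the charge,
ASA, volume and energy scales are conventional choices (His +0.5; Tien
et al. maximum ASA; Zamyatnin volumes; Fauchere-Pliska transfer
energies), not values with a single canonical source.

**Higher levels.** Motif, domain, family, reaction, pathway and GO
features count the cell line's kinase mutations annotated to the entity
("mutations perturbing" it). Gene level adds per-gene mutation counts
and expression/copy-number passthrough on the scale of the input table;
missing expression values are zero-filled with a log message, which
keeps downstream products defined. Sample-level categoricals are
dummy-coded with k-1 indicators against the lexicographically first
level.

## Interaction terms

Five classes of products enter as candidates:

* **drug x mutation** — fingerprint bit x residue-level feature, only.
  Products of drugs with higher-level features (a substructure times
  "lung development") have no mechanistic reading and are never built.
* **PPI** — expression(A) x expression(B) for STRING-style edges with
  combined score strictly above 700, non-self, touching at least one
  kinase, both genes expressed. The product tracks the putative
  complex's abundance.
* **reaction / pathway / GO** — products of same-level perturbation
  counts, excluding pairs related by ancestry anywhere in the ontology
  hierarchy (transitive closure via igraph; a cycle is an error naming
  the offending nodes).

Each candidate is tested individually by the nested-model F-test with
both main effects present: F = ((RSS_reduced - RSS_full)/1) /
(RSS_full/(n-4)), p from F(1, n-4). Testing against the main effects --
rather than the marginal product-only regression -- is what makes the
retained term an *interaction* in the ANOVA sense. Tests are pooled
across drugs and cell lines within a cancer group (per-drug tests
rarely reach the 30-observation support floor). Benjamini-Hochberg
FDR < 0.05 and at least 30 non-zero values are both required; terms
under the support floor are skipped before testing since the filter is
conjunctive anyway. The null calibration of the test is verified by
simulation in the test suite.

## Feature screening and selection

**VIF screening.** For feature *i*, VIF_i = 1/(1 - R^2_i), with R^2_i
from regressing the feature on the rest; VIF > 5 (R^2 > 0.8) flags
collinearity. Screening is stepwise in a priority order: fingerprint
bits before descriptors, later (complex) bits before earlier (simple)
ones, because a single bit maps to one substructure and stays
interpretable inside interaction terms. A candidate is accepted only if
every already-kept feature still satisfies the bound after it joins --
an exact greedy recomputation, deterministic and row-order invariant.
Co-expressed genes are screened the same way among themselves, with the
same threshold.

**Lasso with BIC.** The glmnet Lasso path (columns standardized
internally) proposes a nested family of supports; each distinct support
is scored by BIC = k ln(n) - 2 ln(L-hat). L-hat is defined as the
model's *maximum* likelihood, so it is computed from the least-squares
refit of the support under Gaussian errors with plug-in variance RSS/n
-- using the shrunk Lasso fit itself would penalize large true effects
twice. Ties go to the sparser end of the path. The refit coefficients
double as the model's linear view. An ensemble alternative averages
four ranks (absolute correlation, an RReliefF-style nearest-neighbor
relevance score, permutation importance of a plug-in ridge regressor,
Lasso entry order) and takes the same number of features as Lasso-BIC
chose; ties break by feature name.

## The network

Hidden sizes follow the geometric pyramid rule: ceil(N^(1/2)) (single
layer), ceil(N^(2/3)) and ceil(N^(1/3)) (double), N and ceil(N^(1/2))
(complex double). Ceilings are computed in exact integer arithmetic
because floating-point cube roots of perfect cubes land above the
integer (27^(1/3) = 3.0000000000000004 would give 4). Activations are
TanH with a linear output node and biases at every layer.

Training minimizes MSE/2 + lambda * sum(|w|) over non-bias weights by
BFGS (`stats::optim`), with |w| smoothed as sqrt(w^2 + 1e-8) for
differentiability. Under 10-fold cross-validation each fold picks
lambda from a small logarithmic grid (1e-4, 1e-3, 1e-2 by default) by
held-out loss; optimization runs in 10-iteration chunks and stops early
when held-out loss fails to improve by 1e-6 between checks. The
reported model is refit on all data with the penalty that won the most
folds. Initialization, fold assignment and therefore all weights are
deterministic functions of the seed. If mean CV R^2 is below 0.8 the
schedule escalates: (single, 200 iterations), (single, 300),
(double, 200), (double, 300), (complex double, 200), (complex double,
300), stopping at the first pass and otherwise returning the best seen,
flagged. Mean CV R^2 (not full-data R^2) is the escalation criterion,
matching the cross-validated reporting of every other metric.

## Evaluation and explanation

R^2 = 1 - RSS/TSS and RMSE score the regression. For sensitivity
classification, thresholds {-4, -3, -2, -1, 0} each induce labels
(sensitive iff actual log-IC50 < t, so the classification score is the
*negated* prediction -- lower IC50 means more sensitive), an ROC AUC is
computed per threshold (pROC), and the scalar summary is the mean over
non-degenerate thresholds; averaging across several cuts avoids the
optimistic bias of a single lenient one. Single-class thresholds are
skipped and recorded.

`perturb_effect` raises one feature by one unit in every row and
reports the change in mean prediction: exactly the coefficient on the
linear view, a finite-difference attribution through the forward pass
for the network. PPI terms get a signed edge table with a configurable
strong/weak cut at |delta| = 0.05 (an exposed choice, not a canonical
value; a delta of exactly zero files under "weak positive").
`interaction_analysis` reuses the engine's F-test for one
fingerprint/residue pair and adds the four cell means (bit 0/1 by
residue delta positive vs non-positive) for an interaction plot. Model
families are compared by a two-sided Wilcoxon signed-rank test on
paired per-group scores; all-zero differences short-circuit to p = 1.

## Cohort rules and edge conventions

Thresholds from the screening literature are applied strictly: MW < 900,
KINOMEscan control < 5, STRING score > 700, duplicate-assay r > 0.7
(r exactly 0.7 excludes), group size >= 1000, support >= 30 (29
rejects). Duplicate pairs merge by weighted mean -- replicate counts
when a `weight` column exists, otherwise equal weights, degenerating to
the arithmetic mean -- and the merged row carries the source flag of
the higher-weight measurement (the Sanger assay on ties); merging is
idempotent. Cell lines need whole-genome-sequenced mutation profiles,
>= 30 response entries, an expression profile, and >= 1 mutation mapping
to a reference-PKA position. Lung splits into NSCLC (adenocarcinoma,
non-small cell, squamous cell, large cell, giant cell, mixed
adenosquamous carcinoma) versus "lung (others)"; the
haematopoietic-and-lymphoid group splits by primary histology. Unknown
sites pass through verbatim rather than dying on a whitelist.

## The synthetic generator

`simulation_spec()` defaults describe a mid-sized cancer-group training
set: 40 drugs x 50 cell lines = 2000 responses, 32 Bernoulli(0.3)
fingerprint bits, 20 genes (10 kinases), log-normal(0, 1) expression, 8
GO terms with one parent-child edge, a charge-varying mutation hot spot
at PKA position 187 (40% of lines) plus Poisson background mutations,
and five planted effects: Fingerprint_30 (+2.0), EXP_G01 (+1.2), the
source-flag batch effect (+0.65, the size of the assay-center shift
seen in real screens), PKA_187_CHA x Fingerprint_12 (+1.5), and
EXP_G02 x EXP_G03 (+0.6). Noise is Gaussian with sigma set from the
realized signal so the variance-ratio SNR is 10. The expression sdlog
of 1 is both typical of tumor-line expression heterogeneity and
necessary for identifiability: with nearly homogeneous expression an
expression product is almost collinear with its two main effects and no
method could attribute the planted effect to the product. Collinear
blocks (a descriptor equal to a bit sum; a gene equal to a gene sum)
are planted to exercise the VIF screen, which must remove exactly them.

What passing the synthetic suite shows: the pipeline's stages compose
correctly, planted supports are recovered (recall 1.0 over 20 seeds at
these conditions), linear-view coefficients are consistent, and the
cross-validated network reaches the escalation target. What it does not
show: performance on real screens, where responses are not generated by
the model's own linear form, effects are weaker and denser, fingerprints
are correlated by chemistry, and expression has batch structure none of
which the generator emulates. The generator also makes no attempt to
match the empirical IC50 distribution of any public screen.

## Problem sizes and runtime choices

The packaged study conditions (2000 responses, ~1400 tested interaction
candidates, ~150 design columns, 10-fold CV on a 3-point lambda grid)
were chosen so a full pipeline run completes in a few seconds on one
CPU and the 20-seed recovery study in a couple of minutes, while still
exercising every stage at realistic relative scales (more candidates
than responses per feature, more features than the selection keeps by
an order of magnitude).

## Known limitations

* The F-test screen is marginal: a term needed jointly but not
  marginally can be missed, and three-way interactions are out of scope.
* BFGS with a smoothed L1 penalty does not produce exactly-zero network
  weights; sparsity in the network is soft, unlike in the Lasso stage.
* The escalation schedule evaluates architectures sequentially; it does
  not revisit earlier stages with the later stages' penalties.
* Expression is consumed on its input scale; any normalization is the
  caller's responsibility.
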