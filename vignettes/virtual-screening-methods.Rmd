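---
title: "Methods: ligand-based virtual screening for dietary CYP3A4 inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based virtual screening for dietary CYP3A4 inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypscreen)
library(dplyr)
```

CYP3A4 is the main human cytochrome P450: it carries out phase-I metabolism
of over half of prescribed drugs, of steroid hormones and bile acids, and of
a huge variety of dietary compounds. Because intestinal CYP3A4 sees food
constituents at high concentration for hours, dietary inhibitors can alter
drug exposure (food--drug and herb--drug interactions). This package
implements a desk-scale pipeline for finding candidate dietary inhibitors:
curate public high-throughput bioassay data into labels, train a
fingerprint-based classifier, gate its predictions with an applicability
domain, screen a food-compound library, flag probable intestine-local
inhibitors with Lipinski's rules, and quantify in vitro confirmation
experiments by IC50 regression.

This vignette records the model choices, parameter meanings, numerical
decisions and known limitations. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## Structure handling

All chemistry is delegated to OpenBabel (the `obabel` executable):
canonical SMILES, average-atomic-mass molecular weight, atom-contribution
logP, hydrogen-bond donor/acceptor counts (`HBD`, `HBA2` definitions), and
hashed fingerprints in FPS format. The package only tokenises SMILES strings
for bookkeeping (fragment splitting at `.`, heavy-atom and carbon counts for
the desalting rule, and a well-formedness pre-check that rejects strings
with unbalanced brackets or unpaired ring closures, which some toolkits
silently "repair").

Desalting keeps the largest carbon-containing fragment, breaking ties by the
canonical string that sorts first, so results are order-independent and
deterministic. Entries whose input holds two or more *organic* fragments are
treated as mixtures ("fragmented") and removed during curation rather than
desalted; entries with no organic fragment are inorganic and removed.
Protonation states are not adjusted: structures are used as drawn. This is a
documented divergence from workflows that assign protonation at pH 7.4 with
commercial tools; descriptor values for ionisable compounds shift
accordingly.

Descriptor conventions matter for the rule-of-five filter: published
compilations often use proprietary AlogP/HBA conventions that differ by one
or two counts from OpenBabel's. One convention must be used consistently
within a run; the filter therefore consumes supplied descriptor columns when
a library carries them (as the shipped published hit table does) and
computes them otherwise, recording the provenance per row.

The default fingerprint is the circular, radius-2 extended-connectivity
family (`ECFP4` in diameter naming) — the standard choice for
Tanimoto-distance applicability domains — at OpenBabel's fixed 4096-bit
width; the path-based `FP2` (1024 bits) and the keyed `MACCS` set are
selectable. Models, domains and screening sets must share one configuration;
mismatches are refused at predict/screen time.

## Curation rules

Dose-response bioassay records are labeled *active* when the curve class is
the full high-efficacy inhibition code (-1.1) **and** efficacy is at least
80% of control (configurable), *inactive* when the curve class is the
inactivity code (4.0); every other curve class is inconclusive and excluded.
Duplicates are resolved on the canonical desalted structure: same-label
duplicates collapse to one entry (lexicographically smallest id retained),
conflicting-label duplicates are removed entirely. The observed potency
range of the actives is retained as metadata only — labeling is by curve
class, never by potency.

The stratified split shuffles each class under a seed and assigns
`round-half-up(fraction x class size)` to training (remainders favour
training), keeping the active:inactive ratio equal across splits to within
one compound per class. A split that would empty either side is refused.

## The activity model and its index

The reference backend for this kind of classifier is a closed commercial
deep-learning module; any open replacement is an approximation by
construction, and no attempt is made to reproduce its published
validation-set scores. The package's default engine is
elastic-net-regularised logistic regression on fingerprint bits (glmnet;
penalty chosen by seeded cross-validation, `alpha = 0.5`, folds fixed by the
seed). On sparse hashed fingerprints this family is a strong, fast and fully
reproducible QSAR baseline, and its coefficients are inspectable
(`tidy()`). A single-hidden-layer neural network engine (`nnet`) is
available where a nonlinear decision surface is wanted — practical with
compact fingerprints such as MACCS keys, since its dense weight matrix
scales with the bit width; its budget is capped in optimiser iterations,
not wall-clock time, so results are hardware independent.

Class imbalance (about 1:5 active:inactive in the curated data this mirrors)
is handled by inverse-class-frequency observation weights. Weighted fitting
estimates a *balanced-class* posterior, which inflates scores of the rare
class; the emitted prediction index is therefore calibrated back to the
training prevalence by shifting the logit by `log(n_inactive/n_active)`.
This keeps the conventional screening threshold of 0.7 conservative — the
high-specificity, low-false-positive operating regime a prioritisation
screen wants. The threshold rule is inclusive (`index >= 0.7` is a hit) and
configurable; hit sets shrink monotonically as the threshold rises.

## Evaluation metrics

Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, enrichment
factor `EF = precision / prevalence = [TP/(TP+FP)] / [(TP+FN)/N]`, and
Matthews correlation
`MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
EF-as-precision-over-prevalence is the standard screening enrichment factor
and reproduces, within rounding, the published EF on the validation
confusion matrix implied by the published SE/SP of the reference study —
the exact formula behind that number is shown there only as an image, so
this reconstruction is documented as inferred. Degenerate denominators give
`NA` with a flag, except MCC which reports 0 by the usual convention. The
ROC AUC is the midrank Mann--Whitney statistic, invariant under monotone
transforms of the index.

The literature-consistency check classifies annotated hits as confirmed
(IC50 at or below 20 uM, censored annotations honoured) or refuted and
reports TP/FP. Published compilations sometimes classify a borderline
potency against the grain of the single printed number (the shipped hit
table contains one such compound at 20.9 uM recorded as confirmed); a
recorded per-compound call column can therefore override the numeric rule,
and the shipped table carries the published calls.

## Applicability domain

All `n(n-1)/2` pairwise Tanimoto distances among training fingerprints are
enumerated exactly (no approximate nearest neighbours; desk-scale `n`). With
grand mean `m`, the below-average subset is `{d : d < m}` — strict
inequality, falling back to the whole set only when every distance equals
the mean (then `sigma = 0`). The domain threshold is `APD = d + Z sigma`
from that subset's mean and standard deviation. `Z` defaults to 0.5, the
conventional multiplier for this construction; it is recorded in the fitted
object and should be reported with results. A screening compound is
*reliable* when its nearest training neighbour lies within the APD; the
gate is applied before thresholding, so out-of-domain compounds can never
be hits regardless of index. Two empty fingerprints are defined to be at
distance 0.

## Screening funnel and the intestinal filter

`run_screen()` gives every curated library compound a record: prediction
index, nearest-neighbour distance, reliability flag, descriptors (supplied
or computed), rule-of-five violation count, exclusion reason if any, and
the hit call (`reliable & index >= threshold & not excluded`). The funnel
counts (input, curated, in-domain, above-threshold, hits, intestinal
candidates) are attached for reporting. Exclusion lists (e.g. pesticides or
drugs that should not be called dietary hits) are user-supplied, by
structure or id; the default is empty because such curation is inherently
manual.

The intestinal filter counts strict violations of Lipinski's four criteria
— MW > 500, logP > 5, HBD > 5, HBA > 10 — so boundary values (MW = 500,
HBD = 5) do not violate. Compounds violating two or more criteria are
unlikely to cross the intestinal epithelium; among predicted inhibitors
they are flagged as candidate *intestine-local* inhibitors, the compounds
whose effect rodent models (which lack intestinal CYP3A4) would miss.

## Dose-response analysis

Activity is percent of the vehicle-control fluorescence gain:
`100 (sample_T20 - sample_T0) / (control_T20 - control_T0)`; a non-positive
control delta is a hard error. IC50s come from least-squares fits of the
four-parameter logistic in log concentration, fitted to all replicate
points rather than their means. Defaults follow the common analysis-package
family: asymptotes free within `0 <= bottom <= top <= 120`, Hill slope in
[0.05, 20], IC50 parametrised on the log scale. Initialisation: asymptotes
from the extreme-concentration means, IC50 from the interpolated
50%-of-span crossing, Hill slope 1. The optimiser is bounded
Levenberg--Marquardt (`minpack.lm::nls.lm`); the higher-level `nls`-object
wrapper is avoided because it fails spuriously on zero-residual
(noise-free) data. Non-convergence and degenerate solutions (IC50 at the
search bounds, collapsed span, negative R²) are reported as
`converged = FALSE` with a diagnostic — never a silent number — and fits
whose data never bracket 50% are flagged `extrapolated`.

A fixed-asymptote (100/0) variant is selectable. For *normalized*
percent-of-control data the control defines 100% by construction, and the
constrained fit is the recommended estimator; the package's synthetic
recovery benchmark therefore uses it. With free asymptotes the same
benchmark's median error roughly doubles, driven by sub-micromolar IC50s
whose lower plateau the 0.17--125 uM dilution series barely covers — worth
knowing when designing real assays.

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth without any external download. A small fragment grammar (~40 ring
systems, linkers and decorating groups, assembled with per-molecule ring
numbering) produces valid, parseable SMILES. An acyl piperidine-amide
fragment serves as the planted "active substructure"; whether it was
planted is recorded in the manifest and is the ground-truth
structure--activity rule. Configurable fractions of salt forms, planted
duplicates and inorganic species exercise the curation rules.

Defaults are fixed at the study conditions the pipeline mirrors: a
substructure prevalence of 0.17 with activation probability 0.92 given the
substructure and 0.013 without it, giving an expected active fraction of
about 0.165 — the 1760:8893 class imbalance of the curated reference
dataset. Active records get curve class -1.1, efficacy uniform in [80, 100]
and potency log-uniform in [0.032, 15.85] uM; inactives get curve class 4.0;
an optional fraction receives inconclusive curve classes. Dose-response
curves are 4PL values at the assay's seven 3-fold dilutions
(125 ... 0.17 uM) with Gaussian noise per replicate.

What the generator does *not* emulate: real medicinal-chemistry space
coverage, activity cliffs, assay-specific artefacts, tautomerism and
protonation effects, or correlations between structure and curve-class
quality. Passing the synthetic benchmarks therefore demonstrates that the
pipeline's machinery is correct and well-calibrated under a learnable rule;
it does not certify performance on real bioassay data, whose published
headline scores came from an external dataset and a closed model and are
not reproduced here.

Benchmark problem sizes are chosen for a desk machine: training libraries
of 2000 compounds, fresh screening libraries of 1000, five (tests) or three
(acceptance script) seeds, and 200 simulated dose-response curves.

## Known limitations

* OpenBabel's descriptor conventions differ from proprietary AlogP/HBA
  implementations; exact reproduction of published descriptor tables is out
  of scope (supplied descriptor columns are honoured instead).
* The classifier is an open replacement for a closed backend; its scores on
  the public bioassay data are not comparable to the published model's.
* The curated exclusion list behind a published post-screen hit reduction
  is manual and irreproducible; the mechanism is provided, the list is not.
* Tautomers, 3D conformers and protonation-state enumeration are out of
  scope throughout.
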