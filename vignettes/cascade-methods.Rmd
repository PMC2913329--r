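---
title: "Methods: the cascaded SVM + structural-alert mutagenicity classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cascaded SVM + structural-alert mutagenicity classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The Ames test — bacterial reverse mutation in *Salmonella* Typhimurium — is
the standard experimental assay for mutagenicity, with an inter-laboratory
reproducibility of roughly 85%. Statistical structure–activity models can
approach that ceiling in overall accuracy, but their errors are symmetric:
a mutagen predicted safe (a false negative, FN) costs the same to the
optimiser as a harmless compound predicted toxic. For screening and
regulatory use the FN is the error class that matters. The usual remedies —
class weights, shifted decision thresholds — buy FN reduction at a steep,
diffuse false-positive price, because they perturb the decision boundary
everywhere.

`amescade` takes a different route: leave the statistical model at its
accuracy optimum and bolt a knowledge-based layer *behind* it. Compounds the
C-SVC predicts positive are accepted as `mutagenic`. Predicted negatives —
now a pool depleted of easy mutagens — are re-screened by two serial
checkpoints of structural alerts (electrophilic toxicophores). An
*enhancing* alert relabels the compound `mutagenic`; failing that, a
*suspicious* alert labels it `suspicious`, a warning whose binary reading is
left to the user (`max_accuracy`: treat as non-mutagen; `min_fn`: treat as
mutagen). Compounds passing both checkpoints are `nonmutagenic`. Since the
checkpoints only ever move compounds toward the positive class, the
cascade's FN count is bounded above by the bare SVM's, by construction; the
monotone-safety property is asserted in the test suite rather than assumed.

Key modelling assumptions:

* alert knowledge is *complementary* to the descriptors — alerts are useful
  precisely where the statistical stage is blind;
* out-of-fold (cross-validated) predictions of the training set are a fair
  proxy for the model's behaviour on new data, and therefore a fair basis
  for deciding which alerts help;
* a compound whose descriptors cannot be computed is reported
  `unpredicted`, never defaulted into a class.

## Descriptors (25 by default)

Four global descriptors plus 21 atom-type counts; all are invariant to atom
renumbering, and all are computed on the hydrogen-depleted graph of the
standardized (largest-fragment, charge-as-drawn) structure.

* **Gmin** — minimum electrotopological state over heavy atoms, with the
  Kier–Hall intrinsic state \(I = ((2/N)^2\delta^v + 1)/\delta\) and
  perturbation \(\sum_j (I_i - I_j)/r_{ij}^2\), \(r_{ij}\) = topological
  distance + 1, summed within a fragment. For the degenerate single-heavy-
  atom molecule \(\delta = 0\) is undefined; we substitute \(\delta = 1\)
  and flag the record rather than fail the compound.
* **idwbar** — Bonchev–Trinajstić mean information content of the
  distance distribution. Several variants exist in the literature; the
  default is the magnitude-based form \((W\log_2 W - \sum_k g_k k \log_2
  k)/W\) (W = Wiener number), with the equality-based entropy form
  available behind `variant = "equality"`. Single-atom graphs yield 0.
* **ALOGP** — atom-contribution octanol/water logP. We implement the
  Wildman–Crippen parameterisation of the Ghose–Crippen atom-contribution
  scheme (first-match classification over ~70 element/environment classes,
  hydrogens included) because it is the variant with a widely available
  independent implementation, letting the suite assert equivalence to
  1e-3 on a hand-picked panel. An unclassifiable atom (outside C/H/N/O/S/P/
  halogens) raises a per-record descriptor failure, never a silent zero.
* **nrings** — the cyclomatic number, bonds − atoms + components.
* **atom-type counts** — Kier–Hall E-state fragment types, each pinned to a
  full bonding signature (element, aromaticity, attached H, counts of
  single/double/triple/aromatic heavy-atom bonds), which makes the table
  disjoint by construction and lets overlaps be rejected at load time. The
  shipped default of 21 types covers common C/N/O/Cl/Br environments. The
  identity of the 21 counts used by the original implementation is not
  recoverable from its text, so the table is a runtime configuration
  (`load_atom_types()`): exact parity requires loading that list.

Normalisation is max-abs per column, fitted on the training set only and
serialized with the model; prediction-time matrices are never re-fitted.
All-zero columns receive factor 1.

## The statistical stage

C-SVC with RBF kernel via libsvm (e1071), `scale = FALSE` because scaling
is owned by the descriptor stage. Defaults \((C, \gamma) = (8, 16)\) are
the published calibration for this descriptor set; `tune = TRUE` re-runs
the classic exponential grid search \(C \in 2^{-5..15}\), \(\gamma \in
2^{-15..3}\) scored by stratified 10-fold CV accuracy, with ties broken
toward smaller \(C\) then smaller \(\gamma\) (favouring regularisation).
No class weights are used: FN reduction is the cascade's job, not the
margin's. Fold assignment is stratified by label and seeded; a fold draw
that would leave a single-class training split is re-drawn a bounded number
of times before erroring. Ten folds are used both for tuning and for the
rule-selection predictions.

## Rule selection

Each of the 30 alerts is audited on the cross-validated predicted negatives
of the training set: `caught_fn` counts true mutagens it matches there,
`generated_fp` true non-mutagens. With adequate support
(`caught_fn + generated_fp >= min_support`, default 5):

* `enhancing` ⇔ `caught_fn > generated_fp`;
* else `suspicious` ⇔ `caught_fn >= 1` and
  `caught_fn >= suspicious_floor * generated_fp` (default floor 0.25);
* else `unused`.

A low-support rule is trusted only on its literature pedigree: it joins the
enhancing set only if it still catches more than it costs *and* carries the
`literature_fp_rate_zero` flag in the rulebase; otherwise it is `unused`.
The qualitative published criteria ("more FNs caught than FPs generated";
"remarkable removal power but higher misclassification rate") leave the
numeric thresholds open; `min_support = 5` and `suspicious_floor = 0.25`
are this package's operationalisation, surfaced as arguments and recorded
in the model object. The partition is a pure function of the audit table
and these knobs, and is monotone in `caught_fn` (more catches never demote
a rule) — both properties are tested.

## The alert rulebase

Thirty mutagenicity rules in the Benigni/Bossa (Toxtree) lineage, shipped
as an editable YAML file: per alert, one or more SMARTS (fire on ANY
match), optional exception SMARTS (a match vetoes), the zero-FP literature
flag, and provenance notes. The original SMARTS are not printed in the
source literature, so the shipped encodings are best-effort and versioned
with the package; the file format accepts an explicit `partition:` block so
an externally published enhancing/suspicious assignment can be dropped in
verbatim. Matching is delegated to OpenBabel's SMARTS engine; one fired
alert suffices for a checkpoint (no vote counting), and checkpoint 2 is
only consulted when checkpoint 1 stayed silent.

## Evaluation conventions

Three-output confusion matrices keep `unpredicted` compounds in a separate
column, outside every statistic's denominator. Binary statistics fold the
suspicious column per policy; empty classes yield `NaN`, never 0.
Percentages are reported to one decimal. The stratified splitter uses
(label × sorted fired-alert profile) as the stratum key when a rulebase is
supplied — a reproducible, seedable proxy for the "major functional groups"
stratification of curated Ames corpora, whose concrete scheme is not
public. FN reduction between two models on the same set is
\((\mathrm{fn}_{ref} - \mathrm{fn})/\mathrm{fn}_{ref}\), `NaN` when the
reference has none.

## The synthetic generator, and what passing on it means

`generate_molecules()` produces deterministic labelled sets: a molecule is
a chain of 1–3 benign units (alkane, aromatic, ether, ketone, alcohol,
amine blocks, each unit ending in an attachable atom so concatenation is
always valid SMILES), onto which an alert fragment (nitroaromatic, aromatic
amine, epoxide, alkyl halide, nitrosamine, aldehyde, Michael acceptor, ...)
is grafted with probability 0.9 for mutagens and 0.1 (the decoy rate) for
non-mutagens; 56% of labels are mutagen, mirroring curated Ames corpora.
The compositional scaffolds matter: the polar units share atom-type signals
with the alert fragments, and the combinatorial context diversity keeps the
RBF stage from simply memorising every alert environment — so, as with real
chemistry, some alert-bearing mutagens end up as statistical false
negatives, which is the population the checkpoints exist to rescue. Under
these defaults the pipeline reproduces the qualitative structure of the
real-data study (SVM cross-validated accuracy ≈ 82–83%, FN reductions of
roughly 15–40% across seeds).

What the generator does **not** emulate: real chemical diversity,
three-dimensional effects, property distributions of any benchmark corpus,
label noise of the assay, or mechanistically grounded mutagenicity. Green
tests demonstrate that the machinery — descriptors, calibration, audit,
cascade, evaluation — behaves as specified, not that any particular
real-data accuracy would be attained. Reproducing the published full-data
numbers additionally requires the original 4204-compound dataset, its
descriptor matrix and its alert subsets, which are external downloads; the
ingestion paths for them (descriptor-CSV training with an explicit
train/test tag, rulebase partition blocks) are implemented and tested on
synthetic stand-ins.

## Numerical and engineering choices

* Standardization keeps the largest covalent fragment, collapses explicit
  hydrogens and keeps charges as drawn (nitro groups written
  charge-separated stay so); it is idempotent.
* Unparseable records are retained with a failure flag through every stage
  and surface as `unpredicted` — input row order is never broken.
* OpenBabel stops a batch conversion at the first bad SMILES, so parsing
  proceeds in rounds, dropping exactly the offending entry each time.
* SYBYL MOL2 marks delocalised acyclic bonds (carboxyl, amidinium) as
  aromatic; true aromaticity is recovered by requiring ring membership
  (non-bridge bonds).
* Problem sizes in the test suite are chosen for a laptop-class run: unit
  fixtures of 40–150 molecules, one seeded 1000-compound end-to-end set in
  the acceptance checks (matching the generator's default n), grids of a
  few points in tuning tests.
* Model bundles serialize the SVM, scaling factors, descriptor order,
  partitioned rulebase and audit report together, stamped with the package
  version and a partition hash.

## Known limitations

* Rulebase fidelity is best-effort; alert-level parity with the original
  expert system is bounded by the unavailability of its exact SMARTS and
  its 12 + 4 subset membership.
* The default atom-type list is a plausible 21-type choice, not the
  original's (see above); descriptor-level parity needs that list.
* No applicability-domain estimate and no probability calibration are
  provided; the cascade emits labels and provenance, not confidences.
* Exotic elements (Si, B, metals beyond desalting) fail descriptor
  computation by design and yield `unpredicted`.
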