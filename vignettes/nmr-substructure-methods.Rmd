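---
title: "Determining molecular substructures from 1D NMR shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining molecular substructures from 1D NMR shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrsubstr)
```

## The problem

A 1D NMR spectrum assigns each observed nucleus a chemical shift (ppm)
that is highly sensitive to the atom's chemical environment. Reading a
spectrum backwards — from shifts to the substructures that produced
them — is the slow, expert-driven step in structure elucidation.
`nmrsubstr` frames this as per-atom multiclass classification: given a
carbon's shift (or a hydrogen's, through its attached carbon), its
multiplicity, the other shifts in the same molecule, and the
experimental conditions, predict a discrete code for the atom's
immediate chemical environment.

Two substructure encodings are provided.

**Neighbor labels.** Each carbon's one-bond environment is encoded as
eight integers: four element codes (1--31 in alphabetical symbol order,
0 for an empty slot; see `element_table()`) and four aligned bond
orders (1--3; 0 for no bond). Hydrogens are removed from the slots, so
the bond-order sum falls short of four by the number of attached
hydrogens — the multiplicity channel carries that information instead.
Canonicalization sorts the occupied (bond, atom) pairs ascending with
empty slots trailing, so any enumeration of the neighbors yields one
spelling. Finally every element other than C, N and O is consolidated
into the shared class 32, collapsing chemically rare neighbors. A
hydrogen inherits the label of its single attached carbon; hydrogens
bonded to anything else (hydroxyl, amine) are rejected for `1H` work.

**Ordered SMARTS classes.** Each atom is assigned the first entry of an
ordered SMARTS pattern list that covers it; unmatched atoms fall into a
catch-all class. Because first-match assignment makes order
significant, the package ships the published post-optimization orders
for both nuclei (`default_smarts()`), a baseline ordering rule
(aromatic patterns first, longer before shorter, ties alphabetical),
and `optimize_order()`, which scores the baseline plus `n_perm` (100 by
default) random permutations with a user-supplied validation-accuracy
function and keeps the best, never returning an order that scores below
the candidates it actually evaluated. Atom-level SMARTS matching itself
is delegated to RDKit through a bundled Python helper; the toolkit
perceives aromaticity on its own copy of the molecule, so kekulized and
aromatic connection tables match identically.

## Featurization

One training row per signal. The fixed input is the signal's own shift
(ppm, unrounded), its multiplicity code (s/d/t/q to 1--4, absent 0),
and the experimental conditions: field strength and temperature
normalized to maxima learned from the training split (falling back to
700 MHz and 323 K, which reproduce the reference values 50/700 =
0.07143 and 298/323 = 0.9226 when a split carries no metadata), and the
solvent as a frequency-ranked integer code or an equivalent one-hot
vector. A missing condition is always encoded as 0. The variable input
is the molecule's full shift list sorted ascending with multiplicities
co-permuted; equal shifts are ordered by (multiplicity, atom index) so
the sequence is deterministic. Sequences are zero-padded to the longest
training molecule with a validity mask.

Whether shifts and multiplicities enter the recurrent branch as one
interleaved stream or as two channels is not dictated by the encoding;
this implementation fixes them as two aligned channels per timestep,
which keeps the padding mask shared between them.

## Models

Three architectures are implemented from scratch in base R (dense,
1D-convolution + max-pool, simple-recurrent and LSTM layers with full
backpropagation), because no deep-learning framework is available to
the package; the layer gradients are verified against central finite
differences in the test suite.

* `mlp_lstm` — the variable input passes through two stacked
  bidirectional LSTM layers (50 units per direction; forward and
  backward final states concatenated to 100), then two dense layers of
  250 and 500 units; the fixed input passes through its own 64-unit
  dense branch; both are concatenated at the 500-node point and
  finished by a 100-unit layer and an m-way softmax.
* `mlp_rnn` — identical wiring with simple tanh cells.
* `cnn` — the padded two-channel sequence passes through two
  convolution blocks (32 then 64 filters, kernel 3, each followed by a
  pool of divisor 2 that leaves ceiling(N/2) positions), is flattened,
  concatenated with a 64-unit dense encoding of the fixed input, and
  finished by a 128-unit layer and the softmax. The fixed-input branch
  matters: without it the handful of condition columns is diluted among
  hundreds of flattened convolution features and the network
  under-uses the metadata.

Training minimizes categorical cross-entropy with Adam at library
defaults; SGD, Adadelta, AdaGrad, RMSprop, AdaMax and Nadam are also
implemented for `grid_search()`, which exhaustively evaluates a
hyperparameter grid under 3-fold cross-validation (ties broken toward
the smallest batch, then the fewest epochs). Defaults: 120 epochs
(inside the 100--150 window where validation accuracy plateaus in this
kind of task), batch size 64. Recurrent models use bucket-by-length
batching: rows are grouped by sequence length each epoch and each batch
truncates its padding to the batch's longest sequence — under the mask
algebra this is an exact no-op on results and saves most of the
recurrent work. Inputs are standardized internally on the training rows
(padding positions stay exactly zero); the scaler travels with the
fitted model. With a fixed seed and single-threaded BLAS, fits are
bit-reproducible.

All three fits return an `"nss_model"` object with `print()`,
`summary()`, `predict()` (probability rows summing to 1, argmax ties
toward the lowest class index) and `plot()` (training history) methods.

## Evaluation

Predictions and one-hot truths are flattened to label vectors (argmax
with low-index ties), tallied into an m-by-m confusion matrix whose
entries sum to the number of test instances, and summarized as overall
accuracy (trace over total) plus micro-averaged precision, recall and
F1 (TP/FP/FN pooled across classes before dividing). For single-label
data the four numbers coincide — each false positive for one class is
a false negative for another — and the test suite asserts that
identity on random inputs. Per-class top-k tables report the fraction
of each class's instances whose true label ranks within the k highest
probabilities; `count_poor_classes()` counts classes above a support
floor whose top-k accuracy falls below a threshold (defaults: support
> 10, threshold 0.10). A note on dimensions: the matrix is indexed by
class, not by test instance; the per-class TP/FP/FN/TN formulas only
cohere under that reading, which is the one implemented.

Vocabularies are always built from the training split; a test-time
label never seen in training maps to a reserved unknown class that
models cannot predict, so such instances count against accuracy rather
than silently inflating it.

## The synthetic generator

`generate_synthetic()` produces desk-scale datasets with the
statistical shape the pipeline assumes, so every stage is testable
without a database download. Molecules are random acyclic
valence-respecting graphs (palette defaults: C-rich with N and O;
bond orders drawn 0.88/0.12/0 for single/double/triple); four named
real structures (beta-sitosterol, caffeine, aspirin,
cyclopropylbenzene) are available through `curated_molecules()` for
encoder demonstrations, with synthetic shifts only. Each carbon's
shift is

> base(consolidated label) + solvent offset + field and temperature
> terms + Gaussian noise,

with base shifts spaced 10 ppm apart in separable mode (spacing must
exceed 6 noise SD; default noise 0.5 ppm), solvent offsets of -10/0/+10
ppm and small linear field/temperature terms (1.5 and 1.0 ppm at full
scale). Multiplicity always equals the true attached-hydrogen count,
and conditions can be dropped independently at a configurable rate
(default 0). Everything is reproducible from the seed.

Base shifts are assigned to grid slots by a rule that matters for the
metadata experiment: classes sharing an attached-hydrogen count (hence
a multiplicity symbol) occupy contiguous slots, with frequent classes
at the block center and rare ones at the edges. Because the solvent
offsets equal the slot spacing, a hidden solvent aliases each class
onto its grid neighbors; the blocked layout ensures those neighbors
share the multiplicity (so the multiplicity channel cannot resolve the
alias) and that the slots whose shifts would betray the solvent —
block boundaries and grid ends — belong to rare classes.

What this emulates — and does not. The generator guarantees a
learnable, separable shift-to-substructure mapping and a metadata
effect that exists by construction (the ±10 ppm solvent offsets alias
each class onto its neighbors when the solvent is hidden, which is
deliberately larger than real solvent effects so the ablation has an
unambiguous signal). Real shifts overlap heavily between environments,
depend on ring currents and longer-range structure, and their
condition effects are subtler; passing the synthetic benchmark
therefore demonstrates that the pipeline, encodings and optimization
work — not that these accuracies transfer to database-scale spectra.

`oracle_classifier()` is the analytic ceiling: nearest base shift after
subtracting the known condition terms. With conditions visible it is
essentially exact; with them hidden its accuracy drops by construction,
bounding what any model could do.

## The metadata benchmark

`metadata_benchmark()` is the package's scaled-down analogue of
comparing models trained with and without experimental-condition
metadata: 200 molecules, separable bases, condition effects on; CNN and
MLP+LSTM each trained twice with identical seeds — conditions included
versus zeroed — and scored on a held-out 20% split.

Designing a benchmark where the metadata effect is real took care,
and the shipped construction reflects three findings worth recording.
First, class structure must match the corpus size: the generator's
full palette yields dozens of substructure classes over ~900 training
signals, most with under ten examples, and held-out accuracy then
measures label sparsity rather than the metadata effect. Second, long
shift lists leak the conditions: with four or more carbons per
molecule, the joint likelihood of the shift list over the three
solvents identifies the solvent for over 90% of molecules no matter
how base shifts are arranged, so an ablated model can recover nearly
everything. Third, multiplicity leaks too: if any multiplicity symbol
has a unique class (as the methyl does in an all-carbon world), one
such atom pins the solvent for its whole molecule. The benchmark
therefore uses small C/O molecules (2--3 heavy atoms, single bonds,
5 well-supported classes), 1.5 ppm noise, the multiplicity-blocked
slot layout described above, and one-hot solvent input.

```r
bm <- metadata_benchmark(seed = 1)
print(bm)
```

At these sizes the four fits complete in about a minute on one CPU.
The with-conditions models reach held-out accuracy 1.0 against an
oracle ceiling of 1.0; the single-shift oracle without conditions
drops to ~0.53, and the ablated models — which still see the full
shift list and exploit within-molecule class co-occurrence — recover
much of that but stay strictly below their condition-aware twins
(~0.98). The published experiments this mirrors show an
eleven-point gap on real data; desk-scale synthetic data cannot
reproduce that magnitude, because what makes real ablations costly is
the breadth of real class-conditional shift distributions, so the
benchmark asserts the direction and the mechanism, not the size.

## Numerical choices and degenerate inputs

* Equal shifts tie-break by (multiplicity, atom index); argmax and
  rank ties break toward the lowest class index; these conventions make
  every pipeline stage deterministic.
* Aromatic (order-4) bonds are kekulized by backtracking assignment
  before neighbor encoding; SMARTS matching uses the un-kekulized copy.
* Implicit hydrogens are completed from standard valences (C4 N3 O2
  S2 P3 halogens 1 B3 Si4); elements without a table entry get none.
* Serialized shifts carry 12 significant digits, so write/parse
  round-trips are lossless to ~1e-12 relative error and re-serialization
  is byte-stable.
* Malformed SDF records are skipped with a warning and counted, never
  aborting a stream; records whose signals point at missing atoms or at
  the wrong element for the declared nucleus are likewise skipped.
* A training loss that becomes non-finite aborts with a diagnostic
  rather than continuing to a silently broken fit.
* Degree->4 carbons and hydrogens not bonded to exactly one carbon are
  rejected at encoding time with the record identified.

## Problem sizes used by the shipped checks

Unit tests run the encoders on generated corpora of 10--60 molecules;
the evaluation identities use 1,000 random instances over 20 classes;
the benchmark uses 200 molecules (~420 carbon signals) and trains
four networks at the default 120 epochs; order optimization is checked
exhaustively on 4-pattern lists (24 permutations). These sizes were
chosen so the whole suite runs comfortably on a single CPU while still
exercising every code path at non-trivial scale.

## Known limitations

* Shift physics is not modeled; base shifts are arbitrary separated
  constants, so absolute ppm values carry no chemical meaning.
* The neighbor encoding sees a one-bond radius only — stereochemistry,
  charges and ring context are invisible, exactly as in the encoding it
  implements.
* 1H support classifies through the attached carbon and zeroes the
  multiplicity channel; free-standing heteroatom protons are out of
  scope.
* SMARTS matching requires a Python interpreter with RDKit on the
  PATH; everything else is pure R.
* The published full-database accuracies depend on the complete
  nmrshiftdb2 corpus and are intentionally not reproduced here; the
  package reads the same record dialect, so pointing it at a full
  export is supported but unvalidated.
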