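---
title: "Annotating small-molecule structures from HSQC spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating small-molecule structures from HSQC spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(peakfinger)
```

## The problem

A 2D ¹H–¹³C HSQC experiment gives one cross-peak per proton-bearing
carbon, at coordinates (δH, δC) in ppm. Because chemical shifts are
sensitive fingerprints of local covalent structure, an HSQC spectrum is
close to a structural barcode: experienced spectroscopists recognize
sugars, aromatic rings, or aldehydes at a glance. `peakfinger` automates
that recognition. It maps a peak list to three predicted chemical
properties — a 6144-bit circular-environment (Morgan-style) fingerprint,
the molecular weight, and a compound-class distribution, plus a glycoside
probability — and then ranks candidate structures from a reference
library by the cosine similarity between the predicted fingerprint and
each candidate's true fingerprint. The goal is dereplication: recognizing
that an isolated compound is known, or close to a known one, before
committing to full structure elucidation.

## Spectrum encoding

Peak lists are rasterized onto a fixed 128 × 128 grid. Normal HSQC
spectra give a one-channel image; multiplicity-edited spectra give two
channels (positive phase — CH/CH₃ — and unknown phase in channel 1,
negative phase — CH₂ — in channel 2). Unknown phases count as positive
because CH/CH₃ dominate typical spectra.

The ppm frame is fixed and global: ¹H 0–12.8 ppm, ¹³C 0–230 ppm, high
ppm at the top-left as in conventional spectrum display. A fixed frame —
rather than per-spectrum, signal-dependent bounds — is what makes images
comparable across compounds, which a single shared network requires. The
defaults cover the extremes seen in natural products (e.g. an aldehyde CH
at δC/δH 207.6/9.73). The mapping for a peak at (h, c) is

    row = floor(128 · (c_max − c) / (c_max − c_min)),
    col = floor(128 · (h_max − h) / (h_max − h_min)),

clamped to the frame, so out-of-range peaks land on the nearest edge
pixel rather than erroring. Peaks are single-pixel impulses combined by
maximum; an optional Gaussian blur (sd in pixels) is available but
impulse rendering is canonical — line-width conventions belong to
spectrum simulation, not to the model input. Intensities default to 1;
values above 1 are rescaled into [0, 1] per spectrum (after an optional
cap), while already-relative intensities pass through unchanged so that
the max-combine rule keeps its literal meaning.

## Chemical targets

The supervised targets for a structure are:

* **Fingerprint.** Circular environments of radius 0, 1, 2 are enumerated
  on the hydrogen-explicit molecular graph; hydrogens are real graph
  nodes (they enter every invariant and environment ball) with heavy
  atoms as centres. Each distinct environment identifier is hash-folded
  into 6144 buckets; bits are presence/absence. Folding requires no
  reference corpus and keeps the fingerprint deterministic; a curated
  6144-environment vocabulary would be an alternative reading of the same
  width, but it ties the fingerprint to a corpus and adds nothing at desk
  scale. Presence bits (not counts) match a sigmoid/binary-cross-entropy
  prediction head.
* **Molecular weight.** Conventional atomic weights summed over the
  hydrogen-complete molecule, rounded half-up to 2 decimals (water 18.02,
  ethanol 46.07). Rounding *up* in the ceiling sense would bias every
  mass by +0.005 on average and contradict an unbiased predicted-vs-true
  regression, so half-up is used.
* **Class.** Class labels are supplied as data against a configurable
  vocabulary; the package does not re-implement any ontology classifier.
* **Glycoside flag.** Defined by substructure: a pyranose or furanose
  ring whose anomeric ring-carbon bears an exocyclic oxygen (the acetal
  motif of O-glycosides), matched by fixed SMARTS patterns. The flag can
  be overridden by a label column where curated labels exist.

## The network

Both input variants (one- and two-channel) share one architecture
family: a stack of stride-2 (or stride-4 stem) convolutions, each
followed by batch normalization and ReLU, then global max pooling,
dropout, and four fully connected heads — sigmoid for the 6144
fingerprint probabilities, softmax over K classes, an exponential link
for molecular weight (guaranteeing positivity and making the
percentage-error loss act multiplicatively), and sigmoid for the
glycoside probability. The glycoside head is a separate output rather
than a 60th class because glycosylation is orthogonal to the structural
superclass.

Global max pooling is translation-invariant, but chemical shifts carry
meaning in *absolute* position — an aromatic CH and an anomeric CH are
different precisely because their peaks sit in different regions. Two
normalized coordinate channels are therefore appended to the input
(`coord_channels`, on by default), letting pooled detectors be
position-specific. Without them the pooled features could only encode
position through padding artifacts.

The loss is a weighted sum of head losses: binary cross-entropy
(fingerprint, mean over bits), sparse categorical cross-entropy (class),
MAPE = 100·|ŷ − y|/y (molecular weight), and binary cross-entropy
(glycoside). The default weights are all 1. For desk-scale runs
(`desk_loss_weights()`) the fingerprint term is up-weighted (100):
with mean-reduction over 6144 bits the fingerprint's per-logit gradients
are orders of magnitude smaller than the percentage-scale MAPE
gradients, and on a few hundred examples the shared trunk leans towards
molecular weight. Full width-weighting (6144, equivalent to
sum-reduction) over-corrects — the large initial fingerprint loss then
dominates optimization — so an intermediate weight is used.

Training is minibatch Adam (default lr 1e-5, decay 1e-6, dropout 0.2,
batch 16 — the reference setting for corpus-scale training). At desk
scale (hundreds of molecules) the learning rate must be raised to 1e-3;
at 1e-5 the loss would not move measurably within any reasonable epoch
budget. Everything is seeded: weight initialization in `build_model()`,
and the validation split, shuffling and dropout masks from the training
seed — two identical calls give bit-identical histories. Inference uses
batch-norm running statistics with dropout off, so prediction is
deterministic. Validation defaults to a seeded 10% split of the training
set unless explicit indices are supplied.

The exact conv stack is configurable (`model_config()`); the default is
four 3×3 stride-2 stages of 32/64/128/256 filters. The desk-scale stack
(`desk_conv_stack()`) starts with a 5×5 stride-4 stem so that the
expensive first stage runs at 32×32 rather than 64×64, and ends with a
1×1 channel expansion to a 256-dimensional embedding: each pooled
channel is effectively one position-specific peak detector, and the
fingerprint head reads the embedding linearly, so embedding width —
not depth — is what bounds how many peak positions the fingerprint can
resolve.

## Retrieval

Candidates are ranked by the cosine between the predicted fingerprint
*probabilities* and each record's binary fingerprint. Probabilities are
scored raw by default — binarizing at 0.5 throws away ranking
information (a binarize option exists). Predicted molecular weight and
class act as optional pre-filters (a percentage MW window; an
argmax-class filter), both off by default since the headline rates are
defined on fingerprint similarity alone. Ties are broken by absolute MW
difference, then id, making the ranking total and reproducible.

The non-learning baseline matches raw chemical shifts: a query peak may
pair with a reference peak when |ΔδC| ≤ 0.5 ppm and |ΔδH| ≤ 0.05 ppm
(both inclusive), one-to-one. The reported score is
2·matched/(n_query + n_ref). The pairing is computed as an exact
maximum-cardinality bipartite matching (Kuhn's augmenting paths) rather
than greedy nearest-first pairing: the score depends only on the matched
count, greedy pairing is not guaranteed to reach it (a near pair can
block the only admissible partner of another query peak), and peak lists
are small enough that exact matching costs nothing.

## Evaluation

A retrieved structure counts as an **identification** when its
fingerprint cosine against the query's true fingerprint reaches 1.0
(implemented as ≥ 1 − 1e-9 to absorb floating error; distinct molecules
that collide to the same folded fingerprint count as identified — the
definition is fingerprint-level) and as an **annotation** when the
cosine is at least 0.8. Both thresholds are inclusive. Identification
and annotation rate at k are the fraction of queries with at least one
such hit in the top k; precision@k divides the annotated count by k
(even when fewer relevant records exist); recall@k divides by the number
of similar records in the whole database, found by exhaustively scoring
the truth fingerprint against every record; a query with no relevant
record and no retrieved one scores recall 1 by convention. All rates are
macro-averages over queries. Optionally the query's own database entry
is excluded (off by default — self-retrieval is exactly what a
training-library sanity check wants to see).

## Occlusion attribution

To see which peaks drive which predicted substructures, each peak is
removed in turn, the spectrum re-rasterized and re-predicted, and the
signed change in fingerprint probabilities recorded (peaks × 6144).
Removing a whole peak from the list — rather than masking pixels —
matches how a spectroscopist thinks about the experiment and makes the
"null occlusion" exact: if removal does not change the image (e.g. two
coincident peaks), the delta row is exactly zero. Deltas are mapped onto
atoms through the fingerprinting bookkeeping: every bit knows which
environment atoms generated it, and each bit's |delta| is shared equally
among those atoms. The per-peak attribution total therefore equals the
total |delta| over atom-mapped bits (conservation), and the scheme is
sign-agnostic by default with a signed option. Molecular-weight and
glycoside changes are reported per peak but not attributed to atoms.

## The synthetic simulator

Real HSQC corpora are not redistributable at package scale, so all
training and evaluation here run on synthetic data designed to preserve
the *statistical shape* of the task rather than spectroscopic accuracy:

* Structures come from a fragment grammar spanning five
  natural-product-like classes (chromone/phenylpropanoid aromatics,
  saturated terpenoid-like rings, polyketide-like carbonyl chains,
  N-heterocycles, glucopyranosides) with about a third of eligible
  molecules glycosylated. Classes are assigned round-robin, so small
  samples still cover the vocabulary.
* Each hydrogen-bearing carbon yields one peak; quaternary carbons are
  silent. The noise-free position is a deterministic hash of the
  carbon's radius-2 environment into the textbook shift window of its
  category (aromatic CH 6.0–8.5/100–150; anomeric 4.3–5.5/90–110;
  aldehyde 9.3–10.0/185–208; CH₃ 0.5–2.0/5–30; and so on). Identical
  substructures thus produce identical peaks — the regularity the
  network exploits — and because the simulator uses the same environment
  identifiers as the fingerprint, recovering fingerprints from spectra
  is information-theoretically possible by construction.
* Gaussian ppm noise (defaults 0.02 ppm ¹H, 0.4 ppm ¹³C, roughly
  line-width/referencing scale) is added on top, and shifts are clamped
  to the rasterization frame. Phase is negative iff the carbon bears
  exactly two hydrogens.

What this does **not** emulate: real shift physics (solvent and
stereochemical effects, long-range correlations between neighbouring
windows), peak overlap statistics of large rings, intensity variation,
or artifacts. Passing the synthetic benchmarks demonstrates that the
pipeline is correct and that the network can learn a position-to-feature
code at desk scale; it says nothing quantitative about accuracy on real
spectra, which requires a real training corpus.

## The desk-scale benchmark

`run_synthetic_benchmark()` is the package's self-contained experiment:
300 noise-free molecules, an 80/20 train/holdout split, the desk conv
stack trained 50 epochs at lr 1e-3, and an identical run with permuted
training labels. The control shares architecture, initialization, data
and schedule; only the image→label assignment is shuffled, so its
held-out fingerprint cosine reflects marginal bit statistics (common
scaffold bits push it well above zero), and the model-minus-control gap
isolates the learned spectrum→structure signal. Alongside, the benchmark
reports validation MAPE at the first and last epoch, and retrieval rates
of all 300 spectra against the 300-record library, compared with the
analytic expectation of a uniformly random ranking. Problem sizes were
chosen as the smallest at which the learning signal is comfortably
visible on a single CPU in a few minutes; `scripts/acceptance.R` re-runs
exactly this benchmark.

## Numerical choices and degenerate inputs

* Probabilities are clipped at 1e-7 before logs, so a "perfect" loss is
  ~0 within clipping tolerance rather than exactly 0.
* Batch-norm uses eps 1e-5 and momentum 0.99 for running statistics;
  untrained models predict with the init statistics (mean 0, var 1) and
  remain finite on any input, including all-zero images.
* The MW head exponent is clamped to ±20 before exponentiation.
* Max-pool argmax ties break to the first position; ranking ties break
  by MW difference then id; both keep every result reproducible.
* An empty peak list rasterizes to an all-zero image (valid input); it
  is an error only where the operation is meaningless (occlusion,
  baseline matching).
* Molecules are parsed via OpenBabel with explicit hydrogens; kekulized
  bond orders are used in environment hashing (aromatic rings stay
  symmetric under kekulization, e.g. all six benzene carbons hash
  identically). Formal charges are not part of the atom invariant; the
  intended domain is neutral natural products.

## Known limitations

* The network is trained and evaluated on synthetic spectra only;
  headline accuracies on real corpora are out of reach of a
  self-contained package and are not claimed.
* Hash folding can collide distinct environments onto one bit (handled
  consistently in evaluation, where fingerprint-identity defines
  identification).
* The fingerprint ignores stereochemistry and formal charge.
* The baseline matcher treats peaks as points; multiplets and overlap
  are not modelled.
* Checkpoints and reference databases serialize via RDS, which is
  R-specific; the dataset directory format (TSV/JSON) is the portable
  interchange surface.
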