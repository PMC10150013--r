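---
title: "Decoding movements from EEG-EMG channel graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movements from EEG-EMG channel graphs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(corticograph)
```

## The problem

Brain-computer interfaces for motor rehabilitation usually detect only a
coarse motor intention from EEG. Movements, however, are sequences of
sub-actions, and patients recovering from stroke often execute a movement
in a temporally distorted way. To give finer feedback, this package decodes
*which* movement a subject performed (isometric push or pull) *and* how
faithfully its temporal stages were executed, from synchronized EEG (32
channels, 500 Hz) and EMG (8 forearm/arm sites, 1000 Hz) recordings of 3 s
trials.

The pipeline has four stages:

1. **Preprocessing.** EMG is downsampled to the EEG rate, both modalities
   are zero-phase band-pass filtered (EEG 2--40 Hz, EMG 2--100 Hz), and the
   3 s epoch is cut into six contiguous 0.5 s *sub-action segments*, each
   labeled by `(movement, position)` — 12 classes in total.
2. **Graph construction.** Each segment becomes one graph over the 40
   channels. Node features are multitaper band-power fractions; edges are
   the strongest quarter of pairwise ordinal-pattern couplings (SPMI).
3. **Classification.** A Graph Isomorphism Network (GIN) classifies each
   segment graph into one of the 12 sub-action classes.
4. **Time-based ensemble.** A trial's six predicted sub-action labels are
   compared against the canonical label sequence of each candidate
   movement; the best-scoring movement is the trial's label and its score
   (0--100) quantifies execution quality.

## Connectivity: standardized permutation mutual information

For a series $x(t)$, delay-embedding vectors of dimension $n$ and lag
$\tau$ are symbolized by the rank order of their entries (ordinal
patterns). With $P_X(j)$ the empirical frequency of pattern $j$,
permutation entropy is $PE_X = -\sum_j P_X(j)\log P_X(j)$, the joint
version uses simultaneous pattern pairs, and

$$\mathrm{SPMI}(X,Y) = \frac{PE_X + PE_Y - PE_{X,Y}}{PE_{X,Y}}$$

is a normalized coupling measure in $[0,1]$, symmetric, and invariant to
the entropy log base (the package uses natural logs internally). It is
applied identically to EEG-EEG, EEG-EMG and EMG-EMG pairs; for EEG-EMG
pairs it reads as a corticomuscular coupling measure.

Numerical conventions, chosen once and fixed:

* **Ties** in the embedding vector are ranked by order of occurrence (the
  earlier sample ranks lower), the standard ordinal-pattern convention.
* **Degenerate pairs** (joint entropy 0, e.g. two monotone series) have no
  defined SPMI ratio; the default errors, and
  `ordinal_config(degenerate = "zero")` maps them to 0 for pipeline
  robustness. Band-passed physiological noise never triggers this in
  practice.
* **Edge thresholding.** A 40-channel segment has 780 unordered pairs; the
  graph keeps the $k = \lfloor q \cdot 780 \rfloor$ *strongest* pairs.
  With the default $q = 0.25$ this is exactly 195 edges. Retaining
  everything above the 25th percentile would instead keep 585 edges; the
  top-$q$ reading is the one consistent with a 195-edge graph, so that is
  what the package implements. Ties in SPMI are broken lexicographically
  by channel index so edge sets are deterministic.
* **Estimator bias.** At the default segment length (250 samples, $n=5$:
  246 patterns over up to $120^2$ joint cells) the joint entropy is
  heavily undersampled, so SPMI carries a large positive bias (independent
  white-noise pairs measure around 0.6--0.7, not 0). The pipeline uses
  SPMI *comparatively* — ranking pairs within one segment — so a common
  bias is harmless. Tests that check the near-zero limit use long series
  (20 000 samples), where the bias vanishes.

SPMI is computed per 0.5 s segment, matching the granularity at which
graphs are built and classified; segment length is configurable.

## Node features

Each channel contributes a length-7 vector, in fixed order: the power
fractions of Delta (2--4 Hz), Theta (4--8), Alpha (8--15), Beta (15--30)
and Low Gamma (30--40), then total power, then the electrode index (0--31
EEG in montage order, 32--39 EMG) as a raw location code. Band edges are
half-open intervals on the PSD grid so shared edges are counted once.

PSDs come from a DPSS multitaper estimate with time-bandwidth NW = 2 and 3
tapers (computed from the symmetric tridiagonal Slepian eigenproblem and
cached). At 0.5 s this gives a 4 Hz half-bandwidth — coarse for the delta
band, a known resolution limit of short segments; averaging over three
tapers buys variance reduction in exchange.

The total-power denominator is the modality's filter band (2--40 Hz EEG,
2--100 Hz EMG), i.e. the "totality" is the filtered signal itself. EMG
fractions therefore need not sum near 1 (their band extends past 40 Hz).

Because the raw electrode index (0--39) dwarfs the fractions (0--1) in
scale, node features are z-scored per feature over the training set before
entering the network; the constants are stored in the model and reapplied
at prediction time.

## The GIN classifier

Each GIN iteration updates node $i$ as
$x_i' = h\!\left((1+\epsilon)\,x_i + \sum_{j \in N(i)} x_j\right)$
with $h$ a two-layer MLP (Linear → BatchNorm → ReLU → Linear, 64 hidden
channels) and $\epsilon$ a learnable per-layer scalar initialized at 0.
Sum aggregation is the injective choice that gives GIN its discriminative
power. The default depth is $K = 3$ iterations: enough for information to
travel across the sparse 195-edge graphs while keeping the model
desk-scale; it is configurable.

The readout pools each depth's node embeddings by summation (exactly
permutation-invariant), applies a per-depth linear map, and concatenates
across depths $k = 0..K$ — early iterations often generalize better, so
all depths contribute. Pooling before the linear map was chosen between
the two equivalent orderings (both are permutation-invariant with sum
pooling and linear maps); a linear classifier on the concatenation
produces the 12 logits.

Training minimizes the sum of two cross-entropies: the 12-way sub-action
loss and a whole-movement loss whose 2-way probabilities are the
*marginals* of the 12-way softmax over each movement's block of classes.
Marginalization keeps a single output head consistent between both
objectives; with uniform logits the loss is $\log 12 + \log 2$. Adam
(learning rate 0.005), 300 epochs and batch size 128 are the defaults;
training is seeded and bit-reproducible on one device. The backward pass
is implemented analytically in the package and verified against finite
differences in the test suite.

Batch-norm uses standard train/eval semantics: batch statistics during
training (with running-average updates), running statistics at evaluation,
so evaluation-mode predictions are deterministic.

## Time-based ensemble and movement assessment

For a trial with predicted sub-action sequence $M[1..n]$ and a reference
sequence $G$, the score is
$\mathrm{score} = \tfrac1n \sum_i \mathrm{similarity}(G[i], M[i])$, where
similarity is 0 across movements and $1 - |a-b|/n$ within one (here $n=6$,
the segments per trial). Classification scores $M$ against the canonical
in-order sequence of every candidate movement and takes the argmax (ties
broken push-first and flagged). Scores are reported 0--100 by rounding;
the internal value stays in $[0,1]$.

Per-segment predictions are also categorized: **wrong** (movement
mismatch), **close** (same movement, position distance $\le 3$ segments)
or **far** (same movement, distance $> 3$). Group comparisons of per-trial
scores use a two-sided independent-samples t-test — pooled-variance
Student by default, Welch via `welch = TRUE`.

## The synthetic-data generator

No recorded data ships with the package; a generator produces trials with
the statistical structure the pipeline assumes, and its defaults *are* the
study conditions used by the acceptance checks:

* Each EEG channel is a sum of five band-limited Gaussian carriers (one
  per band, white noise filtered to the band) plus white noise
  (sd 0.5). Carrier amplitudes depend on (band, segment, class): alpha
  ramps 1 → 3 across the six segments for push and 3 → 1 for pull, beta is
  the mirror image, theta sits at 2.5 (push) vs 0.8 (pull), delta and low
  gamma stay at baseline. The ramps make every (class, position) pair
  spectrally distinct — recoverable sub-actions — while the theta offset
  separates the movements.
* EMG channels carry broadband 20--100 Hz activity whose envelope ramps up
  during push and down during pull, plus white noise.
* Corticomuscular coupling is planted by injecting one shared 15--30 Hz
  latent series into C3/C4 and into the movement's coupled EMG sites
  (flexors FDS/FCU for push, extensors ECU/ECRL for pull) with a gain that
  ramps across segments — edges that change over time, echoing how
  EEG-EMG connectivity migrates across muscles during a movement.
* The **patient profile** degrades the same model in the clinically
  expected direction: band-weight contrast attenuated to 40%, noise floor
  tripled, coupling reduced to 30%. Nothing else changes, so score
  differences between groups are attributable to signal degradation.

What the generator does **not** emulate: volume conduction and realistic
scalp topography, ocular/muscular artifacts beyond white noise, line
noise, nonstationarity within a segment, or realistic EMG motor-unit
statistics. Passing tests therefore demonstrate that the pipeline recovers
the *kind* of structure it models — class-dependent band power and
coupling — not that it attains any particular accuracy on recorded data.

Trials serialize to a plain-text container (per-dataset directory:
`manifest.tsv` plus one TSV matrix per trial and modality, printed with 17
significant digits so doubles round-trip exactly). A minimal EDF
reader/writer supports interoperability; EDF's 16-bit quantization makes
that path approximate by design. ICA cleanup is exposed only as an
optional delegate hook (`ica_hook`), disabled by default: the package does
not re-implement ICA.

## Problem sizes and reproducibility

The bundled end-to-end checks run at desk scale, chosen once: 60 trials (30
per class), a 4:1 trial-level stratified split, 100 training epochs, three
training seeds; the group-assessment check uses 30 fresh trials per group
scored by a model trained on the healthy profile. At these sizes the
synthetic recovery is comfortable (movement accuracy near 1.0, sub-action
accuracy above 0.9) and the healthy-vs-patient score contrast is large
(p well below 0.05). Every stochastic step — generation, splitting,
initialization, batch shuffling — draws from an explicit seed, and the
pipeline driver records a config hash and seed in every stage manifest, so
reruns reproduce artifacts exactly.

## Known limitations

* SPMI at 250 samples is bias-dominated; absolute values are not
  comparable across segment lengths or embedding dimensions.
* The delta band is under-resolved by the 0.5 s multitaper window.
* The electrode index enters as a raw scalar (then z-scored); a one-hot or
  learned embedding might represent location better, but the feature
  contract fixes length 7.
* The split is stratified by movement only (not by subject), matching a
  cross-subject design where all subjects contribute to training.
* Scores compare against the canonical in-order sequence; they do not
  model legitimate inter-subject timing variation.
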