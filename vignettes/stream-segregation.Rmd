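---
title: "Measuring information segregation in parallel-stream convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring information segregation in parallel-stream convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Primate vision routes different kinds of information — colour, shape,
motion — through partially parallel anatomical streams. A minimal modelling
question is whether such segregation can arise *spontaneously*: if a
feed-forward convolutional classifier is split into N parallel streams with
identical architecture, no cross-talk before the final fully connected
head, and random initial weights, do the streams divide the labour?

`parastream` implements the full measurement pipeline for that question:

1. **`stream_arch()` / `build_model()` / `train()`** — an N-stream, fully
   parallel convolutional classifier (conv + ReLU + max-pool per stream,
   streams concatenated once before the FC head), trained by SGD with
   momentum, cross-entropy loss, and a step learning-rate schedule.
2. **`analyze_filter_bank()`** — per-filter tuning metrics for the first
   (RGB-facing) convolution layer.
3. **`synthesize_mes()`** — activation maximization ("most effective
   stimulus") for deeper filters, whose many-channel kernels cannot be
   read directly, scored with the same colour/spatial-frequency metrics.
4. **`compute_rdm()` / `cross_layer_matrix()`** — rank-normalized
   representational dissimilarity matrices comparing what the streams
   encode, layer by layer.
5. **`with_stream_deleted()` / `rank_walk_auc()` / `permutation_test()`**
   — a stream-deletion experiment quantifying each stream's functional
   contribution per category super-group, with a permutation null.
6. **`run_desk_experiment()` / `run_pipeline()`** — orchestration over
   seeds (one seed = one model instance).

The convolution forward/backward passes and the SGD loop are implemented
in the package itself (Rcpp/RcppArmadillo for the conv arithmetic); the
statistical battery uses base R's `wilcox.test`, `kruskal.test`,
`friedman.test`, `cor.test`, `rank` and `fft`.

## The tuning metrics

For a first-layer kernel with weights $w_R, w_G, w_B$:

* **Colour index.** Let $r_{\min}$ be the smallest of the three pairwise
  product-moment correlations between flattened channels. The index is
  $r_{\min} \times (-0.5) + 0.5 \in [0, 1]$: 0 for a grayscale kernel
  (channels perfectly correlated), 1 for strong opponency. If one or two
  channels are flat the correlation is undefined but the kernel is
  unambiguously chromatic, and the index is set to 1. Kernels that are flat
  in *every* channel ("developed no structure") are screened out first
  (`flatness_test`, tolerance $10^{-6}$ relative to the bank's largest
  channel SD) and carry no indices.
* **Orientation index.** On the 2-D DFT amplitude spectrum of the
  preferred colour channel (the channel with the largest total non-DC
  amplitude; ties resolve R > G > B), amplitudes are summed into six
  30°-wide orientation bins centred at 0°, 30°, …, 150° (half-open
  $[c-15°, c+15°)$, a partition of $[0°,180°)$). With $A_p$ the largest
  bin and $A_o$ its orthogonal bin, the index is
  $(A_p - A_o)/(A_p + A_o) \in [0, 1]$. DC is excluded (the zero vector
  has no orientation), and each conjugate pair of the symmetric spectrum
  is counted once (half weight per member), so no orientation is
  double-weighted; on even grids this also splits Nyquist-aliased pairs —
  whose members sit at reflected, genuinely ambiguous orientations —
  evenly between their bins. A coefficient's orientation is the angle of
  its frequency vector — the axis along which the grating varies.
* **Preferred spatial frequency.** Amplitudes of the preferred channel are
  summed along circular annuli at integer radial frequencies
  $0$ (DC) … $\lfloor k/2 \rfloor$ cycles/filter (nearest-integer radius,
  out-of-range corners folding into the last annulus); the preferred SF is
  the argmax annulus. DC stays in this analysis: responding to uniform
  colour is a real tuning property of a kernel.

The same spectral machinery (`orientation_bin_amplitudes`,
`sf_annulus_amplitudes`) serves kernel-sized and image-sized inputs, so the
MES metrics are computed by literally the same code path. One asymmetry is
deliberate: `mes_preferred_sf()` removes the channel mean before the
transform. An image lives in $[0,1]$, so its mean (~0.5) is an arbitrary
offset of the encoding and would otherwise hand the DC annulus victory for
every stimulus; a kernel's weights are signed and its DC response is
meaningful. A uniform image still reports 0 (DC).

### A discrete-grid caveat

On an $11 \times 11$ grid the DFT lattice has 1-cycle resolution. A
one-cycle Gabor at an oblique orientation (30°, 60°, 120°, 150°) has its
continuous spectral peak exactly equidistant from the two lattice points
whose angles fall in the *neighbouring* bins, so its generating bin can
receive essentially no amplitude — no envelope choice fixes this. The
synthetic Gabor bank therefore recovers orientation exactly for SF ≥ 2
and for cardinal orientations at SF 1, and the package's tests assert
recovery on exactly that representable set.

## Most effective stimuli

`synthesize_mes()` runs gradient ascent on the input image, maximizing the
spatial mean of one filter's post-ReLU activation map. Per step the input
gradient is normalized to unit norm, the image moves by `step_size` and is
clipped to $[0,1]$; a step is only accepted if the objective does not
decrease (rejections halve the step, successes regrow it toward the
initial value), so the objective trace is non-decreasing by construction.
The initial image is uniform random in $[0.4, 0.6]$ around mid-gray,
seed-controlled; filters silent at the initial image (zero gradient) are
returned immediately with a `dead_filter` flag.

The default `step_size = 0.2` with 256 steps was chosen so the ascent can
actually traverse the distance from a mid-gray start to a full-contrast
pattern: at 64 px that distance is tens of unit-norm steps of 0.2, and
with a 0.05 step the budget runs out long before the optimum (we measured
roughly half the attainable objective on planted-filter models). An
optional mild 3×3 binomial blur every few steps suppresses pixel-level
artifacts; it is off by default so the procedure is strictly deterministic
in its seed.

## Representational dissimilarity

`compute_rdm()` flattens each stimulus's activation maps to one vector,
takes $1 - r$ (product-moment) as the raw dissimilarity — the standard RSA
choice; Euclidean distance is available behind the `distance` option —
and then *rank-transforms* the off-diagonal entries onto $[0,1]$ (average
ranks for ties, $(\mathrm{rank}-1)/(n_{\mathrm{pairs}}-1)$). The rank
transform makes the matrix exactly invariant to any strictly increasing
reparameterization of the raw distance, which the tests assert against a
sort-based oracle. RDMs are compared by correlating lower triangles
(`rdm_correlation`); the within-(layer, stream) reference is a split-half
reliability (filters randomly halved, RDM per half, correlation averaged
over 10 splits). Stimulus sets take one eval image per category by
default (`generate_rdm_stimulus_set`), mirroring the one-image-per-class
protocol used at full scale.

## The deletion experiment

`with_stream_deleted()` returns a view of the model in which one stream's
final max-pool output is replaced during the forward pass — elementwise by
0 (`"zero"`), or by the scalar mean of the values it replaces, computed
over all units and images of the current batch (`"mean"`, which preserves
overall activity while destroying the variance across units that carries
information). Weights are untouched; the surviving streams' activations
are bit-identical to the intact model's, which the tests assert.

Per-category top-1 accuracies of the intact and deleted model give
$\Delta$accuracy per category. Categories are sorted by $\Delta$ in
descending order and replotted as a walk: super-category-A categories step
up, B categories step right, tied groups traverse a diagonal. The area
under the walk normalized by $n_A n_B$ is the **rank-walk AUC**: 1 when
deleting the stream hurts only A categories, 0.5 for no super-category
bias. With diagonal tie handling the AUC equals the Mann–Whitney U
statistic over category pairs (ties counted ½), asserted against a
pair-counting oracle to $10^{-12}$; a fully tied table gives exactly 0.5.
Significance comes from permuting super-category labels over the fixed
deltas (default 1000 randomizations), with a two-tailed add-one p-value
$p = \min(1,\, 2\min(p_{\mathrm{hi}}, p_{\mathrm{lo}}))$,
$p_{\mathrm{hi}} = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(N+1)$.

## The synthetic dataset

`generate_dataset()` draws procedurally rendered shapes on a gray
background: radial-profile contours (smooth blobs, $m$-lobed stars,
elongated bars) filled with a hue-coded colour, with per-image jitter in
position, scale and rotation, additive pixel noise (SD 0.02), and 8-bit
quantization. Half the categories ("A") are *hue-diagnostic*: each has a
distinct hue centre (±10° jitter) while contours are drawn from a shared
pool. The other half ("B") are *contour-diagnostic*: each has a distinct
contour while the hue is drawn nearly uniformly. The `diagnosticity`
parameter (default 0.9) sets the weight with which the non-diagnostic cue
is randomized, so a small residual of the other cue remains, as in any
realistic category structure.

Colours use a luminance-constant encoding: mid-gray plus a chroma vector
along the hue's zero-mean opponent direction, so every hue has pixel mean
exactly 0.5. This keeps hue diagnosticity orthogonal to luminance — a
grayscale rendering of the dataset destroys the A-category signal
entirely (asserted by a nearest-centroid oracle), and no stream can
shortcut colour categories through brightness.

The default desk-scale dataset is 20 categories × 100 train / 20 eval
images at 64 × 64 px; it generates in seconds and is a pure function of
(spec, seed) down to file checksums. What it does *not* emulate: natural
image statistics (1/f spectra, clutter, texture), within-category
exemplar variation beyond parametric jitter, or any semantic structure.
Passing the desk-scale experiment therefore shows that the pipeline's
measurements behave as designed and that stream segregation can emerge
when colour and contour carry separable category signal — not that it
must emerge in natural-image training at scale.

## Training conditions and problem sizes

Full-scale defaults mirror the classic recipe (90 epochs, batch 128,
lr 0.01 decayed ×0.1 every 30 epochs — two decays over the run — momentum
0.9, fan-in-scaled uniform init, no normalization layers, dropout off).
The desk-scale defaults compress the same shape: 15 epochs, batch 64,
decay every 6 epochs, on a 2-stream architecture of (16 filters 5×5
stride 2 + pool, 32 filters 3×3 + pool) with a 128-wide FC layer. One
instance trains in a couple of minutes on one CPU and reaches roughly
65–70% top-1 on the 20-category dataset (chance 5%). The multi-seed
experiment uses 5 instances; the spectral, AUC and RDM oracles run on
50 random kernels, 200 random delta tables and 10–50-stimulus sets
respectively.

## Numerical choices and degenerate inputs

* Flat kernels (and streams made entirely of them) are flagged, never
  silently included; a flat colour channel pins the colour index to 1.
* Orientation bins partition $[0°,180°)$ half-open; annuli use
  nearest-integer rounding; both are asserted to $10^{-9}$ against
  brute-force per-coefficient classification, including even-sized grids
  where Nyquist rows are self-conjugate.
* Zero-variance stimuli (undefined correlation distance) are excluded
  from RDMs with a warning; rank correlations over constant vectors are
  reported `NA` rather than fabricated.
* AUC tie order cannot matter (diagonal segments ≡ midranks); all deltas
  tied gives exactly 0.5.
* All randomness flows through explicit seeds (`.Random.seed` is saved
  and restored around every seeded computation), so datasets, training
  runs, splits and permutation nulls reproduce exactly.

## Statistical conventions

Two streams are compared with the two-tailed Mann–Whitney U test, three or
more with Kruskal–Wallis; layerwise RDM profiles across instances use the
Friedman test (paired Wilcoxon for exactly two layers); correlations are
Spearman. The package-wide threshold is α = 0.01, matching full-scale
practice; the end-to-end desk experiment relaxes only the between-stream
filter-index test to α = 0.05, because desk-scale streams have ~16
first-layer filters rather than 48+ and the U test's power at n = 16 is
far lower. Populations are summarized by medians, except the first layer's
preferred SF, whose discrete 0–5 support makes medians collapse; it is
summarized by the mean. No multiplicity correction is applied across
instances; reports carry test names, n, and two-tailedness.

## Known limitations

* Backbones are plain conv/ReLU/max-pool stacks; skip connections and
  normalization layers are out of scope.
* MES orientation selectivity is not quantified (deep MES images rarely
  show clean orientation structure; the colour and SF metrics are the
  informative ones, as at full scale).
* The desk-scale experiment is stochastic by design: segregation is a
  population-level claim over seeds (as it is over instances at full
  scale), not a per-seed guarantee.
* Desk-scale training (hundreds of SGD steps on 16 first-layer filters
  per stream) reliably reproduces the *functional* segregation signatures
  — stream-deletion AUC above 0.5 for the colour-diagnostic
  super-category and between-stream RDM correlation falling along the
  hierarchy — but it is too little optimization to sculpt first-layer
  kernels into the chromatic-blob/achromatic-Gabor dichotomy that full
  -scale training produces; their tuning-index distribution stays close
  to that of random initialization, so between-stream differences in the
  conv1 colour index rarely reach significance at this scale. Measuring
  weight-level segregation needs full-scale training; the package's
  metrics are ready for it.
* One-cycle oblique Gabors are spectrally ambiguous on small grids (see
  above); affected fixtures are excluded from exact-recovery assertions.
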