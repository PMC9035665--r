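---
title: "Age-aware facial-syndrome analysis with synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-aware facial-syndrome analysis with synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agefaces)
```

## The problem this package studies

Image-based recognition of genetic syndromes — Williams syndrome (WS) and
22q11.2 deletion syndrome (22q) being the canonical pair, with a "control"
class of other look-alike conditions and an "unaffected" class — interacts
with patient age in two ways. First, a classifier trained jointly on a
small affected cohort and a large auxiliary pool of unaffected faces may
perform differently across age brackets (infant, child, adolescent, young
adult, older adult). Second, the facial features the classifier relies on
may themselves drift with age: a feature diagnostic in infancy may fade by
older adulthood. `agefaces` implements, at desk scale, the full analysis
loop for studying both effects:

1. a **synthetic cohort generator** producing labelled face-analog images
   whose disease phenotypes drift with age bracket;
2. dataset bookkeeping — one-sixth auxiliary train/test split per age
   bracket and stratified 5-fold cross-validation;
3. a **four-label classifier** trained with soft-label cross-entropy and
   combined into a confidence-filtered ensemble;
4. a **conditional GAN** whose label conditioning factorizes into separate
   disease and age embedding matrices, generating four kinds of synthetic
   augmentation images;
5. **occlusion saliency maps** with per-cell composites;
6. a **permutation test** asking whether the classifier-salient features
   of one disease differ between two age groups;
7. survey-style statistics comparing simulated human raters with the
   model (per-cell accuracy tables, paired t-tests, per-cell permutation
   p-values).

Everything runs on one CPU in minutes. Real photographs are deliberately
out of scope: the synthetic generator provides cohorts whose ground truth
is known exactly, so every downstream claim can be verified against the
generating process.

## The synthetic phenotype world

`phenotype_spec()` describes how images are rendered. Every image starts
from a smooth oval "face" template. Each affected label adds localized
rectangular feature patches; each patch has an `age_profile`, a 5-vector in
[0, 1] scaling its intensity per bracket. The defaults give WS an
age-stable periorbital-analog patch plus a mouth-analog patch that fades in
adulthood (profile 1, 1, 1, 0.3, 0.2); 22q a nasal-bridge patch that grows
with age and a mandible patch that fades; control an age-stable forehead
patch; unaffected has no features by construction. Independent of disease,
the baseline template darkens along a cheek-level band by `age_drift`
(default 0.15 intensity units from infant to older adult), so even
unaffected images carry an age signal for the GAN's age embedding to learn.

Remaining knobs, with defaults chosen to resemble a small curated photo
collection: pixel noise `noise_sd = 0.05`; `grayscale_fraction = 0.2` of
images rendered single-channel and replicated to three channels (mixed
colour / black-and-white collections); `identity_jitter_sd = 1` pixel of
per-identity patch translation, constant across brackets so "the same
person" is renderable at all five ages. Rendering is deterministic: one
master seed, per-image seeds derived by a fixed linear-congruential counter
scheme (`derive_seed`), so cohorts reproduce byte-for-byte.

Two calibration knobs matter for testing. With `noise_sd = 0` and disjoint
feature regions the classes are perfectly separable (a nearest-centroid
oracle reaches 100%), which anchors the classifier tests. And
`spec_age_constant()` replaces every age profile by its mean and zeroes the
baseline drift, making images of one disease exchangeable across brackets —
the null world used to calibrate the permutation test's type-I error.

What the generator does **not** emulate: photographic pose, illumination
and background variation, face detection/alignment artefacts, demographic
structure, within-class heterogeneity beyond translation jitter, and any
correlation between grayscale rendering and class. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly on data with
known structure, not that the desk-scale models would match real-photo
accuracy.

## Cohort bookkeeping

`split_auxiliary()` draws `floor(fraction * n)` test rows per age bracket
(default one-sixth), uniformly at random after shuffling, so a 62,088-image
pool with bracket counts divisible by six splits into exactly 10,348 test
and 51,740 train images. Floor is used per bracket for determinism when
counts do not divide evenly.

`make_cv_folds()` stratifies by the (disease, age) cell — stronger than
stratifying by disease alone, chosen so the rare older-adult cells stay
represented in every desk-scale fold — dealing shuffled cell members
cyclically from a random offset, so per-cell validation sizes differ by at
most one (a 13-row cell yields validation sizes 3, 3, 3, 2, 2). If `k`
exceeds the smallest cell, the function warns and falls back to
disease-only stratification. Identity-aware splitting is available as a
flag-free design choice we did not take: each synthetic identity appears in
exactly one image per cohort, so folds are identity-disjoint by
construction here.

## Classifier and ensemble

The desk-scale backbone is a single-hidden-layer softmax network
(`nnet::nnet`) on block-averaged pixel features: the image is
channel-averaged, average-pooled to an 8 x 8 grid, and flattened to 64
features. This is a configurable stand-in for a convolutional backbone; the
interfaces (`clf_config()`, `train_classifier()`, `predict`) are
backbone-agnostic. Training maximises `sum_ik target_ik log p_ik`, i.e.
**soft-label cross-entropy**: one-hot rows give ordinary cross-entropy, and
blended rows (soft labels such as (0.55, 0.45, 0, 0)) participate directly.
`soft_cross_entropy()` exposes the loss itself, with predictions clipped at
1e-12 before logs; on one-hot targets it reduces algebraically to standard
cross-entropy, which the tests assert.

`train_cv_ensemble()` trains one classifier per fold on the fold's training
rows plus the auxiliary training split plus any generated augmentation
rows. `ensemble_predict()` averages member probability vectors per image,
restricted to members whose maximum predicted probability reaches 0.5; if
no member qualifies, all members are averaged — the filter never abstains,
a choice made so downstream accuracy tables are always defined.
`forced_binary()` restricts a 4-vector to a label pair (ties to the first
element), emulating a binary survey question answered by a 4-label model;
restricting this way can never do worse than mapping the 4-way argmax onto
the pair, a property the tests verify by grid enumeration.

No class reweighting is applied anywhere in classifier training; balanced
batching is a property of GAN training only.

## The conditional GAN and its factorized embedding

The scientific core is the label-conditioning design. Instead of one
embedding row per (disease, age) cell — which starves rare cells such as
older-adult WS — the condition is built from two matrices: a 4 x `e_d`
disease matrix and a 5 x `e_a` age matrix. `make_condition()` concatenates
a convex combination of age rows with a convex combination of disease rows
(age part first); at the full-scale preset `e_d = e_a = 256` the condition
has length 512. Because the age matrix is shared, every training image —
whatever its disease — contributes gradient to its age bracket's row;
`train_gan()` records this in a 5 x 4 `age_grad_audit` matrix (accumulated
age-row gradient magnitude by the disease of the contributing image), which
the tests require to be positive everywhere.

The desk-scale networks are dense: the generator has one tanh hidden layer
plus a linear skip from [latent; condition] to the pixel logits, with the
output bias initialised at the logit of the training-mean image; the
discriminator is a projection discriminator (image-feature layer, an
unconditional score head, and an inner product with learned additive age +
disease projection rows). Training uses four terms (see `gan_config()`),
each a standard stabiliser for small conditional GANs:

* least-squares adversarial loss (real to 1, fake to 0);
* matching-aware negatives — real images paired with within-batch permuted
  labels are scored as fakes, penalising label-image mismatch;
* a paired conditional reconstruction anchor — the fake generated under
  image j's labels is pulled toward image j (weight `recon_weight = 50`),
  anchoring the generator to conditional means;
* a diversity hinge — two fakes sharing a condition are pushed apart until
  their mean squared pixel difference reaches `diversity_margin = 0.005`
  (weight 50), so the latent keeps carrying within-condition "identity"
  variation instead of collapsing onto the conditional mean.

The anchor and hinge were adopted after pure adversarial training proved
unstable at this data size (conditional fidelity varied wildly across
seeds); with them, generated images classify to their conditioned disease
by a nearest-class-centroid check at 100% across seeds, while type-2 sets
(below) retain latent-specific appearance. Every batch holds equal numbers
of affected and unaffected images; the auxiliary pool is capped per bracket
(`aux_per_bracket`, full-scale preset 500) before training. The training
loop itself is compiled (RcppArmadillo, single precision) — adversarial
training is the one hot loop in the package — with tiny magnitudes flushed
periodically so exponentially decaying optimiser moments never reach the
subnormal-float range, where arithmetic is pathologically slow.

### The four fake-image schemes

* **Type 1** (`generate_type1()`): fresh latent per image; per-(d, a) count
  equal to the disease's mean study count over the five brackets,
  round-half-even (the rounding rule is our choice; bracket counts
  (1, 1, 1, 1, 35) give mean 7.8, so 8 per cell) — rare brackets are
  upsampled relative to their real share and each disease's total stays
  close to its study count.
* **Type 2** (`generate_type2()`): one latent, the five age rows stepped
  through; one-hot labels.
* **Type 3** (`generate_type3()`): age progression of "the same person" —
  the age condition moves along the segment from the infant row to the
  older-adult row with weights 1, 0.75, 0.5, 0.25, 0 (three equally spaced
  interior vectors). Interior images are labelled child / adolescent /
  young-adult in order; this assignment is our choice where the design was
  open.
* **Type 4** (`generate_type4()`): a fixed latent and age, with the main
  disease's embedding blended with each other label's embedding,
  `c*e_main + (1-c)*e_partner`; the soft label places `c` on the main
  disease and `1-c` on the partner (`c = 0.55` by default, 0.75 as the
  second preset). Both WS-main and 22q-main blends are generated.

## Occlusion saliency

`occlusion_map()` slides a `window` x `window` mid-gray patch (fill 0.5, a
common occlusion default) with stride `stride`, windows fully inside the
image, and records `p_target(original) - p_target(occluded)` per position:
positive values mark regions supporting the target label. The grid is
`floor((side - window)/stride) + 1` per side — 5 x 5 for a 64 px image at
the 20/10 defaults. Saliency is computed for the image's true label.
`ensemble_saliency()` averages member maps (all members by default; a
`filter_confident` flag applies the 0.5 confidence rule, which we leave off
because the averaging-time filter is a prediction-time device and the
choice is otherwise open). `composite_saliency()` averages maps over a set
of images — one (disease, age) cell of the test set, in the pipeline — and
records how many maps contributed. Statistics always use the raw position
grid; `upsample_map()` provides a nearest-neighbour per-pixel rendering for
display and for image-domain embedders only.

## The age permutation test

For one disease and two age groups with m maps each (10 + 10 in the
reference design), the observed statistic is the Euclidean distance between
the **embeddings** of the two groups' composite maps. The null pools the 2m
maps and redraws a random m/m split `n_perm = 100` times, recomputing the
statistic. The **rank fraction** is the share of null distances strictly
below the observed one (ties sit above; a mid-rank mode exists); the groups
are declared different when it exceeds 0.95 — equivalently, they are "not
statistically different" when the observed distance is smaller than the 5%
tail of the permutation values. Permutations are drawn uniformly without
enforcing distinctness; with C(20,10)/2 ≈ 92k distinct splits, collisions
are negligible at 100 draws.

Two embedders are provided (`map_embedder()`): a seeded Gaussian random
projection of the flattened grid (deterministic, model-free; scaled
1/sqrt(dim) so embedding distances approximate raw map distances by the
Johnson–Lindenstrauss property), and the trained study classifier's
penultimate-layer activations applied to the upsampled, linearly rescaled,
3-channel rendering of the map — the desk-scale analogue of embedding maps
with a pretrained image backbone. The projection embedder is the default in
tests because it makes the statistic's null distribution depend only on
map exchangeability.

Calibration is checked, not assumed: with `spec_age_constant()` phenotypes
the two groups are exchangeable, and across 200 independent replicates the
rank fraction exceeds 0.95 in about 5% of cases (the discrete null puts
5/101 ≈ 4.95% there); with the default age-specific phenotypes the median
rank fraction for infant vs older adult exceeds 0.95 (power). Both checks
run in the acceptance suite at these exact sizes.

## Human-versus-model statistics

`simulate_raters()` stands in for a reader study: each of 15 raters views
each of 10 test images per (disease, age) cell, with correctness an
independent Bernoulli draw at the cell's configured difficulty.
`per_cell_accuracy()` averages over images x raters. `paired_t_test()` is
the closed-form paired t on per-image differences (validated against
`stats::t.test` to 1e-8; zero-variance differences are flagged rather than
silently returning NaN). `cell_permutation_pvalue()` compares model
accuracy against the mean human accuracy of a cell: per permutation round
and per image, the model's correctness is swapped with one uniformly drawn
rater's response and the statistic recomputed; the p-value is one-sided
(model better) with the add-one convention `p = (1 + #{null >= obs}) /
(n_perm + 1)`, so `p` is never 0. The swap scheme and sidedness are
documented design choices — the survey-statistics design space is wide, and
the simulated raters are a stand-in, so the scheme's only obligations are
exchangeability under the null and reproducibility.

`augmentation_comparison()` reports per-class and macro-average accuracy
(percent) for classifier variants sharing one test set, in a fixed column
order (base variant, then one column per augmentation scheme).

## Orchestration and problem sizes

`run_experiment()` chains every stage under one master seed (per-stage
seeds derived with the same counter scheme) and writes all artifacts —
manifests, fold JSON, prediction CSVs, confusion and augmentation tables,
composite-saliency grids, pairwise rank fractions, survey tables, and a
`run.json` log — into an experiment directory. The `desk` preset uses
64 px classifier images (pooled to 8 x 8 features), a 32 px GAN, a study
cohort of ~100 images with undersampled older brackets, 30 auxiliary images
per bracket, 10 test images per cell, occlusion window/stride 16/8, and
100 permutations. The `full_scale` preset records the full-scale
dimensions (448 px classifier input, 256 px GAN, 256/256 embeddings, 500
auxiliary images per bracket, window/stride 20/10); it is provided for
completeness and is not exercised by the test suite.

The test and acceptance runs use deliberately small sizes chosen to keep
the full suite in the tens of minutes on one CPU: 32 px images, a ~100
image study cohort, 3000 GAN iterations, 200 calibration replicates, 11
power replicates, and 5 augmentation seeds. These sizes are stated here as
the package's reference desk conditions; all of them are plain function
arguments.

## Numerical choices and degenerate inputs

* Probabilities are clipped at 1e-12 inside the cross-entropy; generated
  pixels are clamped to [1e-6, 1 - 1e-6].
* `forced_binary()` breaks ties toward the first pair element;
  `rank_fraction()` counts strict inequalities, with an optional mid-rank
  mode for exact ties.
* Empty manifests, single-class training sets, zero-variance paired
  differences, all-zero saliency maps (constant models) and empty cells
  all have defined, tested behaviour.
* All randomness is locally scoped: every function that draws random
  numbers takes a seed, restores the caller's RNG state, and derives
  per-item seeds with a fixed counter scheme, so concurrent pipelines do
  not perturb each other.
* The GAN core trains in single precision; parameters are returned as
  doubles. Reproducibility is per-seed exact on a given platform;
  cross-platform bitwise identity of the trained GAN is not guaranteed
  (BLAS and FMA differences), which is why tests assert properties of the
  trained model rather than weight values.

## Known limitations

* The synthetic world is linear-additive with rectangular features; it
  cannot probe failure modes arising from pose, occlusion by hands or
  glasses, illumination, or demographic confounding.
* The desk-scale classifier is a pooled-pixel softmax network; its
  saliency maps are coarser and more diffuse than a deep backbone's.
* The GAN's reconstruction anchor biases generation toward conditional
  means; sample diversity is maintained by the hinge but is narrower than
  a full-scale adversarial model's.
* The survey statistics operate on simulated raters; nothing here
  validates the difficulty parameters against real reader studies.
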