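---
title: "Methods: molecular-crystal graph networks in xtalgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular-crystal graph networks in xtalgnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalgnn)
```

## The problem

Crystal structure prediction (CSP) for organic molecules searches an
enormous space of unit cells, space groups, and molecular placements for
the packing a compound will actually adopt. Two cheap learned components
can prune that search drastically: (i) a **density model** that predicts,
from a single rigid conformer, the crystal packing coefficient
$c_\mathrm{pack} = Z V_\mathrm{mol} / V_\mathrm{cell}$ the molecule is
likely to crystallize at, and (ii) a **discriminator** that scores an
explicit candidate crystal as "real" (experimental-like) versus "fake"
(generated). `xtalgnn` implements both, together with the crystal
representation, the synthetic negative-sample generators, and the
geometric vdW baseline score they are evaluated against.

## The 12-parameter crystal representation

For a $Z' = 1$ crystal, twelve numbers plus a space-group choice specify
the structure completely (module `lattice`):

* cell lengths $(a, b, c)$ in ångström and angles
  $(\alpha, \beta, \gamma)$ in degrees;
* the fractional centroid $(\bar x, \bar y, \bar z) \in [0,1)^3$ of the
  **canonical conformer** — the molecule whose wrapped fractional centroid
  has the smallest Euclidean norm (no minimum-image convention; ties break
  to the lowest molecule index);
* three orientation parameters $(\phi, \psi, \theta)$ encoding the
  rotation from a **standardized pose** to the crystal pose.

The standardized pose aligns the principal inertial axes (unit masses,
ascending moments) with the Cartesian axes. Axis signs are fixed by
requiring positive overlap with the centroid-to-farthest-atom vector; a
zero-overlap axis (planar molecules) is fixed by the right-hand rule, and
if the resulting frame is left-handed the third axis is aligned with
$-z$ instead, so the returned rotation is always proper. For
near-degenerate inertia eigenvalues the axes are re-oriented inside the
degenerate subspace against the same reference vectors (plus the largest
perpendicular displacement as a secondary reference), keeping the pose a
covariant, deterministic function of the geometry.

The orientation is stored as a **rotation vector** (axis–angle). Any
bijective encoding satisfies the round-trip contract; the rotation vector
is singularity-free for extraction on $[0, \pi)$ and smooth for the
builder, which is what the differentiability contract needs. The builder
(`build_unit_cell()`) rotates the standardized conformer, translates its
centroid to the fractional position, and generates the remaining $Z - 1$
images with the space group's general-position operators in fractional
coordinates, wrapping each image's centroid into the home cell. Away from
wrap boundaries every output coordinate is smooth in the 12 parameters;
`discriminator_param_gradient()` backpropagates the discriminator output
through this entire chain (verified against central finite differences).

Eight general-position tables are bundled (P1, P-1, P21, P21/c, P212121,
C2/c, Pbca, Pna21 — the groups that dominate organic crystal data); any
other group can be supplied as operator strings, e.g. from a CIF. The
fixture generator returns parameters obtained by *extracting* from the
built entry, so `extract(build(params))` is the identity by construction
even when the placed molecule is not the image nearest the origin.

## The crystal graph convolution

A molecule graph connects every atom pair within $r_c = 6$ Å by directed
edges embedded in a zeroth-order spherical Bessel basis,
$e_n(d) = \sqrt{2/r_c}\,\sin(n\pi d/r_c)/d$, $n = 1..32$. No polynomial
envelope is applied: the basis already vanishes at the cutoff, beyond
which edges do not exist.

For crystals, a padding-style construction replaces minimum-image
arithmetic (module `crystal_graph`): atoms of an $N\times N\times N$
supercell ($N = 3$ by default) are labeled 0 (canonical conformer), 1
(within $r_\mathrm{max} + r_c$ of the canonical centroid), or 2
(discarded). Intramolecular edges run among label-0 atoms; intermolecular
edges run strictly outside-in, label 1 → 0. Periodicity is enforced by
overwriting each image atom's state with its canonical counterpart after
every update. Because of this identity the implementation stores states
only on canonical atoms and *gathers* them for image sources — the
overwrite is exact by construction, and the free-standing
`periodic_overwrite()` primitive is tested separately. The module's core
correctness property is checked against an independent oracle: a dense
convolution on an explicit $N = 5$ supercell with no overwrite,
restricted to the central conformer, matches to better than $10^{-5}$.

Because molecules are replicated whole (wrapped by centroid) and an atom
can stick out of its home cell by up to $r_\mathrm{max}$, a supercell
guarantees complete labeling only when the sphere of radius
$2 r_\mathrm{max} + r_c$ fits inside its hull — a sphere of
$r_\mathrm{max} + r_c$ alone can contain an atom whose parent molecule's
cell lies outside, silently dropping a contact (the periodic-oracle test
caught exactly this). When the check fails, `crystal_batch()` grows $N$
(odd, up to 9) until it passes; a strict mode turns the condition into an
error instead.

## Architecture

Atom features (8: atomic number, period, group, electronegativity,
covalent radius, vdW radius, donor and acceptor flags) are concatenated
with the 16 molecule features; the atomic number is replaced by a learned
32-dimensional embedding. Node states of width 256 are updated by
`n_gc = 4` graph convolutions that bottleneck to 128-dimensional
messages built from (target, source, edge) triples, with residual
connections, layer normalization (after the residual, before dropout of
0.1), and leaky-ReLU activations throughout. Readout concatenates max,
sum, mean, and a single-head dot-product self-attention over nodes
(learned query, scaled by $\sqrt{\text{width}}$), then an FC layer; the
output MLP over (graph vector ‖ molecule features) has $n_{gc}+1$
layers. The discriminator keeps all but the last convolution
intramolecular; the final layer is intermolecular only and omits the
residual (`inter_edge_mode = "final_layer_only"`, with `"all_layers"`
available). Weight initialization is variance-scaled uniform under a
single configuration seed; dropout masks and batch order derive from the
run seed, so training is bit-reproducible.

Everything runs on a small reverse-mode autodiff tape written in base R
(no deep-learning framework exists in the target environment). This is a
deliberate trade: desk-scale widths (32–64) and datasets (hundreds of
samples) train in seconds to minutes on one CPU, which is the scope of
this artifact; CSD-scale training is out of scope.

## Fake-crystal generators

Both generators work in reduced-length parameter space,
$a' = a/(Z V_\mathrm{mol})^{1/3}$ — the unique power law that makes cell
volume scale as $Z V_\mathrm{mol}$, so sampled packing coefficients are
invariant to $Z$ and molecular volume (tested by a two-sample KS check
with a doubled-volume conformer). The **Gaussian generator** fits a
12-dimensional multivariate Gaussian (full covariance, small ridge) to a
dataset and samples from it, wrapping out-of-range draws — angles
reflected into (0°, 180°) with a positive-volume fallback, centroids
wrapped into $[0,1)$ — rather than rejecting them, so every draw is
buildable. The **distortion generator** standardizes an existing
crystal's parameters against the dataset statistics (per-parameter
mean/sd — the conventional reading of "standardize according to the data
set statistics"), adds isotropic Gaussian noise scaled by $c_{dis}$
(default 0.1), and destandardizes. $c_{dis} = 0$ returns the input
exactly (short-circuited to avoid a 1-ulp float round trip). At
$c_{dis} \approx 1$ the standardized value is $s_0 + z$: pooled over a
dataset whose standardized parameters are themselves approximately
standard, the marginal is $N(0, \sqrt{1 + c_{dis}^2})$ and the
correlation with the original falls to $1/\sqrt 2$ — this is the precise
form of "essentially random" that the tests assert.

## Scores

* **Smoothed L1** for density regression: $(x-y)^2/2$ inside the unit
  band, $|x-y| - 0.5$ outside; continuous with value $0.5$ at the break.
* **Stretched discriminator score**: the softmax output $p$ is mapped to
  base-10 log-odds $\log_{10} p/(1-p)$, clipped at the odds of the
  largest double below 1, so the score is 0 at $p = 0.5$, antisymmetric,
  strictly increasing, and saturates at magnitude
  $\log_{10}(2^{53}-1) \approx 15.95 \to 16$ at 64-bit precision.
* **vdW overlap score**: over intermolecular pairs within 6 Å between the
  canonical conformer and its images,
  $\min_n\,[-\ln((r_n^{vdW} - r_n)/r_0)]$ with $r_0 = 1$ Å, restricted to
  overlapping pairs and clipped at 14; with no overlap the score is the
  clip value. It decreases strictly as any overlap deepens and is
  invariant under rigid motion. The closed forms of the stretch and vdW
  scores are this package's own choices satisfying every printed
  constraint; the source renders them only as figures.
* **Quantile filter**: linear-interpolation empirical quantile of a
  reference score distribution; the reported number is the fraction of
  candidates strictly below that threshold.
* **Correlation tables** report Pearson r per feature and retain only
  features with $|r| \ge 0.05$ and incidence $\ge 5\%$.

The evaluation reports *relative MAE* as the mean of per-sample
$|{\rm err}|/y$. Under this definition the packing-coefficient and
density errors are identical by construction (the per-molecule factor
$M/(N_A V_\mathrm{mol})$ cancels), which turns the "apparent improvement
going from packing coefficient to density" into a pure regression-R
artifact — exactly the effect the tests demonstrate on synthetic data.
The alternative reading (MAE divided by the mean target) would make the
identity only approximate, which is why it was not adopted.

## The synthetic world

No licensed database is used. `fixture_spec()` defines a deterministic
world: rigid conformers grown as connected clusters (bond-like spacings
1.4–1.6 Å, minimum separation 1.1 Å, C/N/O palette, 4–12 heavy atoms for
crystals), and crystals whose cells respect the space group's crystal
system with volumes set to hit packing coefficients inside (0.55, 0.85).

One feature of real data is emulated deliberately: experimental crystals
are *optimized* packings. Random placements at realistic density almost
always collide; a discriminator shown random "real" crystals and random
fakes has nothing to learn (observed directly during development). The
fixture generator therefore searches candidate placements for minimal
intermolecular vdW overlap and, if needed, expands the cell with the
packing coefficient floored just above 0.55. What a green learning-sanity
test establishes is exactly this: the architecture and training loop can
discover the geometric hallmark of optimized packing (absence of short
contacts) from supercell geometry alone. It does **not** establish
chemical accuracy, transferability to real polymorph ranking, or
CSD-scale performance — the fixtures carry no hydrogen bonding, no
realistic valence structure, and packing coefficients near the lower edge
of the real range.

The planted density dataset labels conformers with a fixed smooth
function of volume-per-atom plus Gaussian noise of $\sigma = 0.01$
(roughly the per-sample error scale a well-trained model reaches on real
data), giving a known achievable-MAE floor of $\sigma\sqrt{2/\pi}$; the
learning test requires approaching it within a factor of two.

## Numerical choices

* Round-trip tolerances: $10^{-5}$ Å for extract/build, $10^{-8}$ for
  rotation recovery, $10^{-10}$ relative for cell volume.
* Degeneracy thresholds: inertia eigenvalues within $10^{-6}$ (relative)
  are treated as a block; axis overlaps below $10^{-6}\times$ the
  geometry scale defer to the secondary reference, then the right-hand
  rule. All-collinear geometries are an error (no frame exists).
* Monte Carlo molecular volume: $10^5$ points over the vdW-sphere union
  with a fixed internal seed. The pose is canonicalized first and the
  sample box made symmetric in $z$ with paired $\pm z$ evaluation, making
  the estimate *exactly* invariant under rigid motion, inversion, and
  atom permutation — without this, forward-pass invariance tests fail at
  the $10^{-3}$ level through the volume feature.
* Empty message sums (no in-edges, or a crystal with no intermolecular
  contact within $r_c$) follow the empty-sum convention: the update is the
  transform of a zero vector, and discriminator outputs flag the
  zero-contact case.
* Adam (lr $10^{-3}$–$3\times10^{-3}$ at desk scale), early stop after 20
  non-improving epochs, best-test-loss checkpoint selection; the paper's
  SI hyperparameters are unavailable, so these are package defaults
  exposed in `run_config()`.

## Known limitations

$Z' = 1$ only; rigid conformers; no temperature/pressure conditioning; no
angular (3-body) edge embeddings; no learned generative models; the CIF
reader covers the common subset this package writes plus simple
small-molecule files, not the full CIF grammar; desk-scale training only.
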