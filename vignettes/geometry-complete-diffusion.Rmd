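---
title: "Geometry-complete diffusion for 3D molecules: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-complete diffusion for 3D molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(moldiff)
```

## The model

`moldiff` implements a denoising diffusion probabilistic model over whole 3D
molecules. A molecule with $N$ atoms is the pair $\mathcal{M} = [X, H]$:
Cartesian coordinates $X \in \mathbb{R}^{N\times 3}$ (Å) and invariant
per-atom features $H$ holding a scaled one-hot element type plus a scaled
integer formal charge. The forward process corrupts a clean latent
$z_0 = [z^{(x)}, z^{(h)}]$ through a fixed variance-preserving Markov chain

$$q(z_t \mid z_{t-1}) = \mathcal{N}(z_t \mid \alpha_t z_{t-1}, \sigma_t^2 I),
\qquad \alpha_t = \sqrt{1 - \sigma_t^2},$$

so that the marginal at any step is available in closed form,
$q(z_t \mid z_0) = \mathcal{N}(\alpha_t z_0, \sigma_t^2 I)$. Conditional
transition moments between two steps $s < t$ use
$\alpha_{t\mid s} = \alpha_t/\alpha_s$ and
$\sigma^2_{t \mid s} = \sigma_t^2 - \alpha^2_{t\mid s}\sigma_s^2$ — the
squared-coefficient form, which is the unique choice satisfying the Gaussian
composition law (the test suite verifies this against a Monte-Carlo
composition oracle). The true denoising posterior
$q(z_s \mid z_t, z_0)$ is Gaussian with

$$\mu_{t\to s} = \frac{\alpha_s \sigma^2_{t\mid s}}{\sigma_t^2} z_0
  + \frac{\alpha_{t\mid s}\sigma_s^2}{\sigma_t^2} z_t, \qquad
  \sigma_{t \to s} = \frac{\sigma_{t\mid s}\,\sigma_s}{\sigma_t},$$

and the learned reverse process replaces $z_0$ by the estimate
$\tilde z_0 = z_t/\alpha_t - \hat\epsilon\,\sigma_t/\alpha_t$ implied by the
network's noise prediction $\hat\epsilon = [\hat\epsilon^{(x)},
\hat\epsilon^{(h)}]$. Training minimizes
$\tfrac12 w(t)\,\lVert \epsilon - \hat\epsilon \rVert^2$ with $w(t) = 1$ and
uniformly sampled timesteps.

### Translation invariance: the zero-CoG subspace

A likelihood over free coordinates cannot be translation-invariant, so the
coordinate channel lives entirely on the linear subspace
$\sum_i x_i = 0$: inputs are centred, the coordinate prior and all coordinate
noise are standard Gaussians *restricted to that subspace* (sampled by
projecting i.i.d. normals), and the denoiser's coordinate output is
re-projected. Dimension counting in the likelihood uses $(N-1)\times 3$ for
the coordinate block. The test suite tracks centre-of-gravity drift over
1000-step ancestral chains (tolerance $10^{-6}$).

### The denoising network

The denoiser is an SE(3)-equivariant message-passing network with two
feature channels per node: invariant scalars and equivariant 3-vector
channels seeded by lifting the noisy coordinates (node-to-centre
displacements; per-edge displacements feed the edge vector channel). On the
fully-connected graph, each directed pair $(i,j)$ carries a local frame

$$a = \frac{x_i - x_j}{\lVert x_i - x_j\rVert},\qquad
  b = \frac{x_i \times x_j}{\lVert x_i \times x_j\rVert},\qquad
  c = a \times b,$$

built on centred coordinates. Projections of the vector channels onto
$(a, b, c)$ are rotation-invariant scalars; because $b$ is a pseudo-vector,
they are *not* reflection-invariant, which is what makes the network
chirality-aware. With `use_frames = FALSE` only norms and $a$-projections
are used and the network becomes exactly reflection-equivariant — the
ablation switch the tests exercise. Note the frame triple is right-handed by
construction ($c = a\times b$), so chirality manifests as the failure of
reflection equivariance, not as a sign flip of $\det[a\,b\,c]$.

Messages are computed by an MLP from sender/receiver scalars, edge scalars
(radial-basis distance features), vector norms, and the frame projections;
a per-edge logistic gate — scalar message attention — multiplies each
message before mean aggregation (`use_sma = FALSE` clamps the gate to 1).
Scalar and vector channels update residually; the vector update combines
frame axes and neighbour vectors with invariant coefficients, so rotation
equivariance holds *exactly*, to machine precision, by construction.

Timestep conditioning appends $t/T$ plus two sine/cosine harmonics to the
node scalars; property conditioning appends one scalar normalized by the
training-set mean and median absolute deviation, stored with the model.

The paper-scale configuration is 9 layers with 256/64 node and 32/16 edge
(scalar/vector) channels. The package's desk-scale experiments use 3 layers
with 48/12 and 8/4 channels — small enough to train on one CPU in minutes,
large enough to recover rigid template geometry to within 0.05 Å.

### Training machinery

No automatic-differentiation framework for R is assumed: the package ships
a small tape-based reverse-mode engine (`R/autodiff.R`) whose operations are
verified against central finite differences, plus an Adam optimizer with
cosine learning-rate decay and an exponential moving average (decay 0.999)
of the parameters used at inference — the standard stabilizer for diffusion
models. Gradient steps accumulate over `batch_size` molecules.

## Sampling, strided sampling, and optimization

Generation draws $z_T$ from the joint prior and applies the learned reverse
step down the full grid $T, T-1, \dots, 0$; the final state is decoded
(argmax element, charge rounded half-away-from-zero) with no extra noise at
$t = 0$. *Time-scaled* (strided) sampling visits only $k$ evenly spaced
timesteps, recomputing the conditional moments between visited steps; with
$k = T$ it is path-identical to full sampling, and with $k = 10$ it
produces deliberately under-refined molecules, which the optimization
experiment uses as its starting material.

Property-guided optimization takes existing molecules, forward-noises them
to an intermediate step $t_{\text{opt}}$ with the closed-form marginal, and
reverse-diffuses to 0 under a property-conditional model with the requested
target value. Atom counts are preserved; both coordinates and types are
optimized. We interpret the entry point this way (featurize, then
forward-noise) because decoded molecules live at the $t=0$ scale; treating
them directly as latents at $t_{\text{opt}}$ would mismatch the marginal
variance.

Numerical choice: large strides amplify denoiser error through the
$1/\alpha_t$ factor in $\tilde z_0$. The sampler therefore clips the implied
clean state elementwise to $\pm 20$ latent units — roughly ten times the
data scale, so ordinary chains are untouched — before the posterior step.
This is the usual static-thresholding stabilization for
$\epsilon$-parametrized samplers.

## Evaluation metrics

Bond inference follows the distance-lookup convention: a pair is bonded at
the highest order whose reference covalent length (pm, orders 1–3) plus the
order-specific margin (10/5/3 pm) bounds the observed distance. An atom is
*stable* when its summed bond orders equal a permitted valence for its
element and formal charge (charge-adjusted entries such as N$^+$ → 4 are
tabled); a molecule is stable when all its atoms are. *Validity* asks less:
the inferred graph must sanitize, i.e. no atom may exceed its maximum
permitted valence (radicals pass, as under the usual cheminformatics
sanitizer; a single free atom is therefore valid but unstable — pinned by a
fixture test). *Uniqueness* counts distinct canonical SMILES among valid
molecules over the total sampled, and *novelty* the fraction of those
absent from a reference list. Canonical SMILES, 3D embedding of SMILES, and
force-field energies go through the Open Babel command-line tools.

The *energy ratio* of a conformer is its UFF energy divided by the mean UFF
energy of `n_conformers` (default 50) conformers regenerated from the same
molecular graph; ratios above 7 flag highly unlikely conformations. The
reference ensemble here is built by canonicalizing the graph to SMILES,
re-embedding with Open Babel's structure generator, and running its
weighted rotor search — a knowledge-based distance-geometry analogue; rigid
molecules yield a single reference conformer. Set-level summaries report
Student's $t$ 95% confidence intervals.

The per-molecule negative log-likelihood assembles the variational bound:
prior KL at $T$, one-draw Monte-Carlo estimates of each per-step KL
(closed-form Gaussian KLs, checked against grid integration at $10^{-4}$),
a reconstruction term at $t=0$ that treats types and charges as integers
under a discretized Gaussian, and $-\log p(N)$ from the empirical size
distribution. Both per-molecule and set-mean reductions are exposed, since
reporting conventions differ.

## The synthetic data generator

`make_toy_dataset()` emulates small molecules by rigidly rotating (uniform
over SO(3) via QR of a Gaussian matrix), optionally scaling, and jittering
chemically plausible templates: a bent water-like triatomic (O–H 0.9572 Å,
104.52°), a methane-like tetrahedron (C–H 1.09 Å), and a linear
acetylene-like chain whose colinear geometry exercises the degenerate-frame
path. Every template must have atom stability 1 under the bundled bond
table at zero jitter — the generator refuses implausible templates. Study
conditions used throughout the tests and the acceptance script, chosen once:
256 training molecules, jitter 0.02 Å, $T = 100$ diffusion steps, one-hot
scaling 0.25 and charge scaling 0.1. The conditional experiments scale the
water template uniformly over $[0.8, 1.3]$ and condition on the mean
pairwise distance, a property that is a strict function of geometry and so
directly measurable on generated output — no external property predictor is
needed at desk scale.

What the toy distribution does *not* emulate: conformational flexibility,
aromaticity and delocalized bonding, heteroatom diversity, size variation
beyond a few atoms, and the bond-typing ambiguity of large drug-like
molecules. Passing the desk-scale suite therefore demonstrates that the
diffusion algebra, the equivariance contracts, the conditioning pathway,
and the metric stack are correct — not that the small network would match
paper-scale sample quality on real corpora; those runs require the external
processed datasets and GPU-scale training.

## Problem sizes and runtimes

The suite trains two 3-layer models (6000 Adam steps, batch 2, ~4 min each
on one CPU), draws 200 full-grid and 200 ten-step samples for the recovery
experiment, runs 20 seeded optimization trials (8 molecules, 10-step
starts, 30-step optimization toward 1.3 Å), and evaluates the NLL on 15
held-out molecules. Acceptance experiments use the same sizes.

## Known limitations

* The denoiser's internals (channel widths, activation and residual
  placement, the exact lift of noisy vectors) follow the published
  construction of geometric vector message passing but are this package's
  own choices behind the stated contract; alternatives fit behind the same
  layer interface.
* Strided sampling at very small $T$ interacts with the schedule's ratio
  clipping; the clean-state clip bounds, but does not remove, the resulting
  error amplification.
* The external-dataset loader expects a documented manifest layout
  (`manifest.yaml` plus per-split XYZ/SDF); the published archives must be
  converted once into that layout. Reference-row reproduction is asserted
  in the acceptance suite only when those corpora are present.
* Validity relies on Open Babel for canonicalization; if the CLI is absent,
  validity itself still computes but uniqueness/novelty raise an
  informative error.
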