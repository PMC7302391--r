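---
title: "Integrated active contour segmentation of GGO lung nodules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated active contour segmentation of GGO lung nodules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggoacm)
```

## The problem

Small ground-glass opacity (GGO) pulmonary nodules are an early
manifestation of lung cancer. On CT they are hazy, sub-solid lesions a few
millimetres across, with low contrast against lung parenchyma, frequent
intensity inhomogeneity, blurred boundaries, and adhesion to vessels and
pleura. Classical region-based active contours (Chan–Vese and relatives)
drive a level-set contour with raw intensity statistics and assume pixels
are spatially independent; on GGO nodules they under-segment blurred
boundaries and leak into adjacent bright structures.

`ggoacm` implements an integrated active contour model that replaces both
inputs of the classical model:

* the **region term** operates on a per-pixel **Markov random field (MRF)
  energy map** instead of raw intensity, injecting spatial label structure
  (a Potts prior) and per-class Gaussian likelihoods; and
* the **boundary term** uses a **Bayesian posterior-probability-difference
  stopping function** from a Gaussian mixture model (GMM) fitted to the
  intensity histogram, instead of the image gradient.

## The model

A contour is the zero level set of $\phi$ ($\phi > 0$ inside). The energy
minimised is

$$
E(\phi) = \lambda_1 \int_\Omega (u - f_1)^2 H(\phi)\,dx
        + \lambda_2 \int_\Omega (u - f_2)^2 (1 - H(\phi))\,dx
        + \mu \int_\Omega S\,\delta(\phi)\,|\nabla\phi|\,dx
        + \nu \int_\Omega \tfrac12 (|\nabla\phi| - 1)^2\,dx
$$

with $H(\phi) = \tfrac12(1 + \tfrac2\pi \arctan(\phi/\varepsilon))$,
$\delta = H'$, $u$ the MRF energy map, $S$ the stopping map, and $f_1, f_2$
the mean of $u$ inside/outside the contour (their stationarity conditions;
see `region_means()`). The fourth term keeps $\phi$ a signed distance
function, so no re-initialisation is ever performed. Minimisation is by
explicit gradient descent (`evolve_step()`, `evolve_contour()`):

$$
\frac{\partial\phi}{\partial t} =
  \delta(\phi)\left[\lambda_2 (u - f_2)^2 - \lambda_1 (u - f_1)^2\right]
  + \mu\,\delta(\phi)\,\mathrm{div}\!\left(S \frac{\nabla\phi}{|\nabla\phi|}\right)
  + \nu \left(\nabla^2\phi - \mathrm{div}\frac{\nabla\phi}{|\nabla\phi|}\right).
$$

### The MRF energy map

The pipeline first clusters normalized intensities with seeded K-means
(`kmeans_presegment()`, $K = 3$: parenchyma, nodule, bright tissue), reduces
the clusters to two MRF classes (below), estimates per-class Gaussian
parameters by EM (`estimate_class_stats()`), and refines the labelling with
a small fixed number of iterated-conditional-modes sweeps under the joint
energy

$$
U(X, Y) = \underbrace{\sum_s \left[\ln(\sqrt{2\pi}\,\sigma_{m_s}) +
  \frac{(y_s - \mu_{m_s})^2}{2\sigma_{m_s}^2}\right]}_{U_1\text{, feature}}
 + \underbrace{\sum_{\langle s,t\rangle} \beta\,[x_s \neq x_t]}_{U_2\text{, Potts}}
$$

with $\beta = 0.5$ on the 8-connected (second-order) neighbourhood. The
energy is computed **once** and frozen; the contour evolution never updates
it. Starting ICM from the K-means labelling keeps this one-shot computation
near a good optimum instead of requiring a full combinatorial MRF solve.

**Assembly of the per-pixel map.** Two assemblies are provided by
`mrf_energy_map()`. The textbook per-pixel evaluation of $U_1 + U_2$ at the
assigned labels (`assembly = "assigned"`) is retained, but it is a poor
region feature: both regions fit their own class about equally well, so the
between-region mean difference is only $\ln(\sigma_1/\sigma_2)$ while the
min–max range is inflated by the $\chi^2$ tail of the quadratic term —
after normalization the map separates the regions *less* than raw
intensity. The default (`assembly = "contrast"`) is therefore the per-pixel
**energy margin between the two class hypotheses**,

$$
u(s) = \Big[U_1(x_s{=}1) + \beta\,n_{\neq 1}(s)\Big] -
       \Big[U_1(x_s{=}2) + \beta\,n_{\neq 2}(s)\Big],
$$

where $n_{\neq m}(s)$ counts neighbours (under the refined labelling) whose
label differs from $m$. The feature part is a quadratic discriminant of the
intensity; the Potts part adds a spatially regularised step of height
$2\beta|\mathcal N|$ between the two regions. This is what makes the map a
contrast-*enhanced* version of the image: on low-contrast inhomogeneous
phantoms the normalized nodule-vs-background separation of the energy map
exceeds that of the intensity image (verified on 20 seeded phantoms in the
test suite). Note the margin map flips sign under a 1↔2 relabelling (the
assigned-label map is invariant); the pipeline fixes class 2 = nodule, so
orientation is determinate.

### The stopping map

Pooled intensities are modelled as a $K$-component GMM
($p(x) = \sum_k \alpha_k N(x \mid \mu_k, \Sigma_k)$, `fit_gmm_em()`, EM in
log space, K-means initialisation, variance floor $10^{-8}$). $K = 3$ lets
vessels/pleura/highlight tissue occupy their own component. With posteriors
$p(k \mid x)$ (`posterior_map()`), the stopping function is

$$ S = \lvert p(\text{nodule} \mid x) - p(\text{background} \mid x) \rvert $$

(`stopping_map()`). $S \to 1$ where either class dominates and $S \to 0$ on
the class-ambiguity locus — the blurred boundary — so the weighted length
term halts the contour where the *gradient* would be too weak to. Which two
components enter $S$ is not determined by the mixture itself when $K = 3$;
the pipeline matches components to the two MRF class means (nearest-mean
matching, `select_components()`), overridable via
`nodule_component`/`background_component`.

### Reduction of three clusters to two classes

The MRF works with two classes ($m = 2$): nodule vs everything else. The
obvious rule "middle-intensity cluster = nodule" (GGO sits between dark
parenchyma and bright vessels) fails in both directions in practice:

* without bright tissue in the field, K-means splits the broad background
  mode in two and the *middle* cluster is upper background (the nodule is
  the brightest cluster);
* with bright tissue, K-means spends one cluster on it and the nodule
  merges with upper background into the *middle* cluster.

`reduce_to_two_classes()` therefore selects a nodule **region**, not a
cluster: each cluster mask is denoised by iterated 3×3 majority voting;
its connected components of plausible size (12 px – 20 % of the image) are
refined against the locally blurred image (threshold halfway between region
core and surrounding ring median, bounded above so bright tissue and its
blurred edge ribbons are excluded, 3×3 opening to cut thin bridges); and
each refined candidate is scored by compactness
($4\pi A/P^2$) × a soft size factor × blurred local contrast × an
intensity-order prior (middle cluster preferred; a cluster of normalized
mean > 0.75 is solid tissue and is excluded as a nodule candidate — GGO is
by definition sub-solid). The winner, holes filled (dark spots from bubbles
or necrosis belong to the nodule), becomes class 2. If no candidate
survives the gates, the middle-mean cluster is used wholesale.

### Initial contour

`init_phi()` builds the initial mask from the nodule class (or the
maximum-posterior component), keeps its largest connected component and
returns its signed Euclidean distance ($\phi = d_{\text{in}} -
d_{\text{out}}$, so `mask == (phi > 0)` exactly; at the centre of a 5×5
square $\phi = 3$, the distance to the nearest background pixel). Starting
near the true boundary is what lets the non-convex evolution reach a good
minimum reliably.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 0.5 | energy/pair | Potts discordance cost; the working range is 0.5–1, larger values smooth more |
| `K` (presegment), `gmm_K` | 3 | – | tissue classes: parenchyma / nodule / bright |
| `lambda1`, `lambda2`, `mu`, `nu` | 1 | – | term weights of the integrated energy |
| `epsilon` | 1 | px | Heaviside/Dirac smoothing width |
| `dt` | 0.1 | – | explicit Euler step; `dt * nu < 0.25` keeps the diffusion-like regulariser stable |
| `max_iter` | 500 | – | iteration cap |
| `conv_tol` | 1e-4 | relative | per-iteration relative change of the integrated energy; stop after 10 consecutive quiet iterations |
| `band` | 6 | px | half-width of the update band around the zero level set |
| `icm_passes` | 1 | sweeps | one-shot MRF refinement before freezing the energy |

`epsilon`, `dt`, `max_iter` and `conv_tol` are numerical choices of this
implementation (no values are inherent to the model); the defaults were
chosen for explicit-scheme stability and are deterministic for a given
configuration. All randomness (K-means and EM starts, phantoms) is
seed-controlled.

## The phantom generator

`make_phantom()` emulates the GGO challenge cases on a 64×64 grid:
background 0.25, nodule at `background + contrast` (default 0.2 — low
contrast), optional outward radial shape perturbation, plus per scenario:
a linear intensity ramp (`inhomogeneous`, peak-to-peak 0.3 — enough to
carry bright-end background up to nodule-like intensities, so purely
global intensity statistics cannot separate the classes), Gaussian
boundary blur (`blurred`, σ = 2 px), a 2-px bright (0.85) vessel touching
the rim (`vessel`), a bright pleural band touching the nodule (`pleura`),
an adjacent non-touching bright blob (`highlight`), and 1–3 dark (0.15)
interior discs whose pixels remain part of the ground truth
(`dark_spots`); Gaussian noise (σ = 0.05) last, clipped to [0, 1]. The
truth mask is the *pre-blur* indicator: the blurred boundary is an imaging
effect, not a change of the object. The benchmark suite (`make_suite()`)
jitters the radius uniformly in 3–8 px (the small-nodule regime), contrast
in 0.15–0.25, and irregularity in 0–0.1, all derived from one master seed.

What the phantoms deliberately do **not** model: anatomy (airways, fissure
geometry), CT physics (quantum noise, reconstruction kernels, partial
volume in 3-D), and radiologist inter-observer variability. Passing the
phantom benchmark therefore demonstrates the *mechanisms* — contrast
enhancement by the MRF energy, boundary localisation by the posterior
difference, robustness to adjacent bright structures — not clinical-grade
accuracy on patient data.

## Numerical choices and degeneracies

* Spatial derivatives: central differences in the interior, one-sided at
  image borders (a replicated-border central difference halves the slope
  there and makes even an exact signed distance function look irregular);
  $|\nabla\phi|$ floored at $10^{-10}$ inside divergence terms.
* Updates are confined to a band $|\phi| \le$ `band` around the contour.
  The $(|\nabla\phi|-1)^2$ regulariser's descent flow is antidiffusive —
  ill-posed — where $|\nabla\phi| < 1$; with the usual flooring it instead
  *diffuses* the kinks of the distance function (its ridges/medial axis)
  and slowly flattens the far field, which the contour never uses. Freezing
  the far field keeps the flow where it is well-behaved; with it, the
  integrated energy decreases in essentially every iteration.
* Convergence is declared on the energy, not on the mask: slow flows (e.g.
  a weak region force on a low-contrast image) can hold a mask unchanged
  for many iterations while still descending; an energy criterion lets
  every configuration run to its own optimum, which also makes ablation
  comparisons meaningful.
* Class/component degeneracies: per-class σ floored at $10^{-4}$, mixture
  variances at $10^{-8}$, weights at $10^{-6}$; collapse is recorded in the
  fit's attributes rather than allowed to go singular.
* Constant images cannot be normalized with the default window (error with
  guidance); an empty or all-image initial mask raises an initialisation
  error pointing at the ROI.
* Energy-map min–max normalization of a constant map returns zeros.
* K-means ties: delegated to `stats::kmeans`; measure zero on noisy data.

## Benchmark sizes

The shipped tests and the acceptance script use 20 phantoms per scenario
(64×64), 10⁴-sample EM recovery checks, and 50–100 random instances for
the quadrature/identity oracles; a full benchmark run takes a few minutes
on one core.

## Known limitations

* 2-D only, single nodule per (ROI-cropped) image; the largest-component
  rule discards multifocal disease.
* The 3→2 reduction is tuned to the GGO setting (sub-solid lesion among
  darker parenchyma and brighter solid tissue); purely solid nodules would
  be excluded by the brightness gate and need an adjusted prior.
* The explicit scheme needs small `dt`; no narrow-band or semi-implicit
  acceleration is implemented.
* On very small nodules (radius ≈ 3 px) single-pixel boundary errors cost
  several IOU points; tail cases in the benchmark reflect this, which is
  why scenario results are summarised by medians.
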