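---
title: "Voxel-wise indirect structural connectivity: models and methods"
author: "viscdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise indirect structural connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscdti)
```

# The problem

A focal brain lesion — a stroke, say — does not only destroy tissue
locally: it severs white-matter fibers that connect distant parts of
the brain, so its functional footprint extends far beyond the lesion
boundary. Conventional voxel-based analyses of diffusion tensor
imaging (DTI) compare local quantities such as fractional anisotropy
(FA) and mean diffusivity (MD) between a patient and a control group,
and are therefore most sensitive near the lesion itself. `viscdti`
implements a voxel-level *connectivity* index designed to amplify
exactly the remote effects those local metrics miss: the voxel-wise
indirect structural connectivity, VISC.

# The connectivity model

Streamline tractography produces a set of fibers, each an ordered
polyline in millimetre coordinates. A voxel is identified by the
location of its center and owns the half-open box
`[center - size/2, center + size/2)`; a fiber *penetrates* every voxel
containing at least one of its points.

For one fiber, the per-fiber matrix connects **all pairs** of voxels
it penetrates (a clique, not just consecutive voxels); the binary
direct matrix $X$ is the union of these cliques over all fibers, made
symmetric with a zero diagonal. The indirect matrix $Y$ marks voxel
pairs that are exactly two hops apart:
$y_{ij} = 1$ iff $i \neq j$, $(XX)_{ij} > 0$ and $x_{ij} = 0$.

Writing $y_{(i)}$ for row $i$ of $Y$ and $\mathbf 1$ for the summation
vector, the index is

$$\mathrm{VISC}_\alpha(i) \;=\; \frac{y_{(i)} X \mathbf 1}{\left(y_{(i)} \mathbf 1\right)^{\alpha}},
\qquad \alpha \in [0, 1].$$

At $\alpha = 1$ this is the *mean* number of direct connections over
voxel $i$'s indirect neighbourhood; at $\alpha = 0$ the denominator is
1 and the index degenerates to the raw numerator (the *total* count,
which behaves much like a fiber-count measure). Voxels without
indirect neighbours get VISC $= 0$ rather than an undefined value, so
"nonzero VISC" is a meaningful support mask downstream.

The six-voxel worked example wired into [make_worked_example()] pins the
arithmetic: voxel A has direct neighbours \{B, C\}, indirect
neighbours \{D, E, F\} with direct-connection counts 2, 2 and 1, so
$\mathrm{VISC}_1(A) = 5/3$ and $\mathrm{VISC}_0(A) = 5$. The fixture's
fiber membership is under-determined by the topology alone; the
package adopts the minimal three-fiber realisation
\{A,B,C\}, \{D,B,E\}, \{C,F\} consistent with every degree and
neighbour relation.

```{r worked-example}
fx <- make_worked_example()
g <- build_connectivity(fx$fibers, fx$grid)
compute_visc(g, alpha = 1)$values[fx$voxels["A"]]
```

Two design points deserve emphasis. First, the clique reading of the
per-fiber matrix is the consequential one — a chain reading
(consecutive voxels only) gives a much sparser graph — and the package
follows the clique definition while exposing `mode = "chain"` in
[build_connectivity()] for sensitivity analysis. Second, both matrices
are stored sparsely over the full grid dimension and $XX$ is computed
in sparse arithmetic; a dense voxel-by-voxel matrix is never
materialised.

# Tensor estimation

Per voxel, the apparent diffusion coefficient along unit gradient
$g_k$ is the log signal loss relative to the unweighted channel,
$\mathrm{ADC}_k = -\ln(S_k/S_0)/b$, and the six unique elements of the
symmetric tensor solve $\mathrm{ADC}_k = g_k^\top D\, g_k$ by ordinary
least squares — the log-linear fit, chosen over nonlinear signal-space
fitting because the estimated quantities are the diffusion
coefficients themselves. Eigenvalues are sorted descending and the
standard FA and MD maps follow from them.

Conventions the model itself does not dictate:

* voxels with any non-positive signal are masked invalid (the log is
  undefined there) instead of raising an error;
* negative fitted eigenvalues, which can occur under noise, are kept
  for FA/MD arithmetic but flagged per voxel, preserving auditability;
* if several unweighted channels are supplied on read they are
  averaged into one.

# Tractography

The tracker integrates the FA-weighted principal-eigenvector field
$v(x) = \mathrm{FA}(x)\, e_1(x)$ bidirectionally from each seed with a
4th-order Runge–Kutta scheme at a 0.1 mm step. A literal per-voxel
"follow the eigenvector of the containing voxel" scheme cannot use a
0.1 mm sub-voxel step meaningfully, so the field is interpolated
trilinearly, with each corner eigenvector sign-aligned to the current
heading before blending (eigenvectors carry an arbitrary sign).

Stopping rules, with defaults in [tracking_params()]:

* **FA floor** (0.15): propagation stops when interpolated FA drops
  below the threshold — low enough to let fibers run into gray matter,
  where converging pathways meet;
* **curvature** (60°): evaluated both per step and over a one-voxel
  look-back, because at a 0.1 mm step the per-step turn through a
  genuinely sharp interface is tiny while the accumulated voxel-scale
  turn is not;
* **volume boundary**;
* **length budget** (140 mm): each half-track is capped at half the
  maximum so a completed fiber respects the total bound.

Seeds sit on a uniform 1 mm lattice anchored at voxel centers and are
kept only where FA strictly exceeds 0.3. After tracking, fibers
shorter than 10 mm or longer than 140 mm are excluded; the boundaries
are kept (only strictly shorter/longer fibers are excluded) and the
comparison carries a $10^{-9}$ mm tolerance so floating-point
accumulation over 0.1 mm steps cannot flip a boundary case. Tracking
is bidirectional (both $\pm e_1$ from the seed) and entirely
deterministic.

# Lesion-aware registration

The registration utilities mirror a processing chain for comparing a
lesioned brain against a reference anatomy:

* **Nine-parameter affine** (3 translations, 3 rotations, 3 scales)
  minimising mean squared intensity difference by gradient descent
  with numeric gradients and a backtracking step, over a
  coarse-to-fine schedule (4, 2, 1 mm working resolutions, block-mean
  downsampling). The schedule and step control are package choices;
  non-convergence returns the best parameters with a warning flag.
* **Histogram matching** before the affine: a monotone remap sending
  source quantiles to reference quantiles through a 256-bin source
  CDF and the inverse empirical reference distribution, so outputs
  take values present in the reference.
* **Demons registration** with the classic fixed-image-gradient force
  and stabilised denominator
  $\delta u = (f - m(x+u))\,\nabla f / (\lVert\nabla f\rVert^2 + (f - m(x+u))^2)$,
  followed each iteration by a regularising Gaussian smoothing.
  Lesion handling: any voxel whose current mapping lands inside the
  lesion mask is frozen for that iteration, and the smoothing is
  *mask-aware* — a normalised convolution over free voxels only — so
  displacements never mix across the frozen/free boundary. "Edge
  preserving" is not otherwise specified anywhere, and normalised
  convolution is the variant that preserves the stated intent: tissue
  surrounding the lesion registers while the lesion content is left
  alone. Voxels on a zero-gradient plateau are skipped.
* **Inverse-field approximation**: the small-deformation field is not
  invertible in closed form, so the inverse is approximated by
  iterating (i) force the inverse at each forward-mapped location to
  point back, nearest-grid assignment with collisions averaged, then
  (ii) smooth with a 2 mm FWHM Gaussian; 10 iterations by default.
  The result carries a per-voxel composition-residual map, its
  mean ± sd, and the per-iteration residual trace, which is
  non-increasing on smooth invertible fields. A uniform translation
  inverts to machine precision in the interior.

# Group statistics

For each voxel the per-control differences
$d_c = \mathrm{control}_c - \mathrm{subject}$ are tested one-tailed
against a zero-mean null with a one-sample Student's $t$
($t = \bar d / (s_d/\sqrt n)$, $\mathrm{df} = n - 1$). Zero-variance
voxels get $t = \pm\infty$ by the sign of $\bar d$. The default tail
per metric follows lesion physiology — FA and VISC drop in and around
a lesion (controls > subject), diffusivity rises (subject >
controls) — and is configurable, as is the voxel-wise level (0.05 by
default; nothing in the protocol fixes it, so set it explicitly for
anything beyond exploration).

One statistical property is worth spelling out: all nine differences
share the single subject map, so the test is *conditional on the
subject image*. Calibration therefore holds when the subject equals
the control population mean (how the test suite assesses it); a
subject carrying independent measurement noise of the same magnitude
as a control inflates the statistic, because $s_d$ estimates only the
control-noise spread. This is an inherent property of the
single-subject-versus-group design, not of the implementation, and is
one reason difference volumes should be compared across subjects
processed identically rather than read as absolute counts.

The count of significant voxels (optionally within a region) is the
difference volume; its natural logarithm is the **LDV**. A zero count
propagates as a missing value — not $-\infty$ — and drops out of
regressions. LDVs and regional means (over all voxels and over the
nonzero-VISC support) are regressed against Fugl-Meyer scores with
slope $F$-tests; multiple regressions judge coefficients at the
Bonferroni-corrected level $\alpha/m$ with $m = 3$ (the three metrics
VISC, FA, MD). For region-of-interest tables it is ambiguous whether
the divisor should also count ROIs, so [roi_analysis()] reports both
the metric-corrected flags (at 0.05 and 0.01, the usual star
convention) and a flag corrected by $m \times n_\mathrm{ROI}$.

The Fugl-Meyer bookkeeping validates subscores against the scoring
table maxima (grand 226; upper extremity 130; lower extremity 96) and
errors on out-of-range values naming the offending domain. Example
score and correlation tables for a ten-subject stroke cohort and an
eighteen-subject FA-correlation comparison ship as TSV under
`inst/extdata/`.

# Synthetic data: what the phantoms emulate

No imaging data ship with the package; every pipeline stage is
exercised on synthetic diffusion signals generated by inverting the
monoexponential attenuation model $S = S_0 e^{-b\, g^\top D g}$, with
Rician noise formed by adding two independent Gaussian channels to the
complex signal and taking the magnitude. Noise seeds derive
deterministically from a master seed, so cohorts are bit-reproducible.
The noise level is a free parameter with default 0; the cohort
examples use $\sigma = S_0/40\ldots S_0/20$, i.e. roughly SNR 20–40,
a realistic range for b = 1000 s/mm² brain DTI — no empirical noise
level is available to copy, and the value is documented as a choice.

Two phantom families cover different needs:

* **Bundle phantoms** ([generate_phantom()]): cylindrical bundles with
  prolate tensors oriented along the centerline tangent, isotropic
  background, optional box/sphere lesions replaced by isotropic
  tensors at twice the background diffusivity (the elevated-MD
  signature of chronic lesions), and optional radial eigenvalue taper.
  Overlaps resolve by first-listed precedence.
* **The tract phantom** ([make_tract_phantom()]): a cylinder whose
  axial eigenvalue is solved per voxel so FA falls off linearly from
  the midpoint toward both termini, emulating a tract entering cortex.
  Because FA varies *along* the fiber paths, streamline extent — and
  with it penetrated volume and VISC — responds smoothly to the FA
  stopping threshold. This is the geometry used for the
  threshold-sensitivity sweep, where the log mean VISC is strongly
  negatively correlated with the threshold.

One subtlety matters at desk scale: in a phantom of parallel fibers of
effectively unbounded length, every penetrated voxel pair shares a
fiber, the indirect matrix is empty and VISC is identically zero.
Real brains avoid this through finite, branching, heterogeneous
tracts. The synthetic studies reproduce the effect by bounding the
fiber length budget well below the tract length, which creates genuine
two-hop structure; sweeps and cohort studies therefore run with
`max_length` around a quarter of the tract extent.

What the phantoms do **not** emulate: crossing or kissing fiber
bundles (the single-tensor model cannot represent them, and the
tracker terminates on the resulting orientation discontinuities),
susceptibility/eddy distortions, motion, partial-volume mixtures at
tissue interfaces, and realistic brain geometry. Passing tests on
these phantoms therefore validate the algorithms and their contracts,
not performance on acquired brains.

# Numerical conventions

* World coordinates are millimetres; voxel indexing is half-open
  around centers, so a point on a shared face belongs to the
  higher-index voxel — one rule, enforced everywhere (seeding,
  penetration, interpolation, scattering).
* Trilinear interpolation clamps to the boundary value inside
  operators that must stay finite (warping, demons) and returns a fill
  value where "outside means absent" (seed FA checks, mask lookups).
* Gaussian smoothing uses separable kernels renormalised over the
  in-volume support, so constant fields are preserved exactly; mass
  conservation holds up to edge renormalisation.
* The integration core is compiled (C++ via Rcpp), as is usual for
  streamline tractography; everything else is vectorised R on top of
  `Matrix` sparse algebra.

The test suite runs the geometry at deliberately small problem sizes —
grids of roughly 20–40 voxels per axis, hundreds of seeds, cohorts of
4–10 subjects, 100–1000 Monte-Carlo replicates — chosen so the whole
suite completes in well under a minute of compute while still
exercising every stopping rule, degenerate case and calibration claim.

# Known limitations

* Single-tensor model only; no crossing-fiber handling (a higher-order
  model would change both tracking and the meaning of VISC in
  multi-population voxels).
* The registration components are small-deformation methods; no
  diffeomorphic guarantees, which is deliberate — lesions can alter
  topology — but means forward/inverse composition is only approximate.
* The one-tailed single-subject design is conditionally calibrated
  (see above) and applies no voxel-level multiple-comparison
  correction.
* Streamline files use a plain-text polyline dialect; binary track
  containers from other tools are not parsed.
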