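---
title: "Models and numerical methods in neurofem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in neurofem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

neurofem implements a complete finite-element (FE) modelling chain for
electromagnetic brain imaging: multi-compartment tetrahedral head meshes
built from triangulated tissue surfaces, EEG and linearized electrical
impedance tomography (EIT) lead fields under the complete electrode model
(CEM), divergence-conforming dipole source stencils, and hierarchical
Bayesian inversion by the iterated alternating sequential (IAS) scheme and a
Gibbs sampler. This vignette records the models, the parameters that
matter, and the numerical and design decisions behind the implementation.

## Forward model

The quasi-static electric potential $u$ in the head $\Omega$ satisfies

$$\nabla\cdot(\sigma\nabla u)=\nabla\cdot \mathbf J^p,$$

where $\sigma$ is the conductivity distribution (element-wise scalar or
symmetric tensor, S/m) and $\mathbf J^p$ the primary (neural) current
density. The same operator drives EIT, with injected electrode currents
replacing $\mathbf J^p$. Discretized with linear nodal elements, the
stiffness matrix is
$A_{ij}=\sum_T V_T\,(\nabla\varphi_i)^\top\sigma_T(\nabla\varphi_j)$,
assembled exactly (constant gradients per tetrahedron). Electrodes follow
the CEM: an electrode $\ell$ with contact impedance $Z_\ell$ occupying the
boundary patch $e_\ell$ contributes the surface-mass block
$M_{ij}{+}{=}\tfrac1{Z_\ell}\int_{e_\ell}\varphi_i\varphi_j\,dS$,
the coupling column
$B_{i\ell}=\tfrac1{Z_\ell}\int_{e_\ell}\varphi_i\,dS$
and the diagonal $C_{\ell\ell}=|e_\ell|/Z_\ell$, with closed-form triangle
integrals. The augmented system
$\begin{pmatrix}A+M&-B\\-B^\top&C\end{pmatrix}$
is symmetric positive semi-definite with the constant vector as its only
null direction.

**Gauge and solver.** Rather than grounding a node, the constant is
projected out of right-hand sides and iterates (deflation), preserving the
SPD structure. Systems are solved by preconditioned conjugate gradients
with the lumped diagonal preconditioner (LDP), $d_i=\sum_j|A_{ij}|$; the
solver accepts an abstract matrix-vector product, so an accelerated backend
can replace the built-in sparse products without touching algorithmic code.
The default relative-residual tolerance is `1e-8` with a `3n` iteration
cap: forward accuracy well below discretization error. Electrode voltages
are reported zero-mean, and EEG lead-field rows are re-referenced to the
common average, making every column gauge-free.

**Electrode patches.** A patch is the set of boundary triangles whose
centroid, projected on the local tangent plane at the (boundary-projected)
electrode center, falls inside the ring annulus
`[inner_diameter, outer_diameter] / 2`, with an axial cap of one outer
radius to keep the patch on the local surface sheet. Nominal electrode
positions lie on the smooth anatomy, which a uniform lattice mesh
approximates to within one cell: electrode centers are therefore snapped to
the nearest boundary-face centroid, and the area-weighted effective patch
centers are exposed (`patch_centers`) so that validation oracles can be
evaluated at the positions the discrete electrodes actually occupy. On
coarse meshes a thin ring may contain no face centroid; such electrodes
raise an error rather than silently degrading, and the scaled EIT studies
use disc electrodes of roughly twice the cell size instead (the 10/7.5 mm
ring geometry is exercised on a fine flat slab, where its patch area
converges to the analytic annulus area within ~5%).

## Mesh generation

`generate_uniform_mesh()` covers the bounding box of the segmentation with
an axis-aligned cubic lattice of the requested resolution and splits every
cube into 6 tetrahedra (the Kuhn split: the six axis-permutation paths from
one cube corner to the opposite one). This split is conforming across cube
faces without parity bookkeeping and yields uniform element shapes.

Elements are labeled by testing barycenters against the compartments in
priority order (lower value = higher priority; ties go to the innermost
compartment of the outermost-first descriptor). Point-in-surface tests use
ray-casting parity with three fixed ray directions and a majority vote,
which tolerates the intersecting, imperfect boundaries real segmentations
produce; the kernel is compiled (C++). When an element's nodes fall in two
or more compartments, the highest-priority compartment among them wins,
which is what lets a thin high-priority layer such as the skull keep its
nominal width at coarse resolutions. Elements whose barycenter lies outside
every compartment are dropped.

Labeled volumes approximate analytic volumes to a few per cent at
`h = r/8`; because the staircase error fluctuates in sign with the grid
parity, the error is *not* monotone under refinement and the tests assert
accuracy bounds per resolution rather than monotone decrease.

**Smoothing.** `smooth_mesh()` evolves compartment-interface and
outer-boundary nodes under the bi-Laplacian flow
$x \leftarrow x - s\,L(L(x))$ with $L$ the uniform graph Laplacian
restricted to same-interface neighbors, while interior nodes follow with
ordinary Laplacian relaxation; any element inversion rolls the sweep back
and halves the step. Smoothing reduces boundary roughness (the radial
standard deviation of a sphere phantom's boundary drops by an order of
magnitude in 10 sweeps) but, like all neighborhood-averaging flows on
closed convex surfaces, it shrinks the domain slightly (~2.5% volume over
10 sweeps on the sphere phantom). The forward-accuracy validations
therefore run on the unsmoothed mesh; smoothing is kept for its intended
purpose, regularizing jagged interfaces of real segmentations.

## Dipole sources: H(div) stencils and PBO

A dipole at an arbitrary position is represented by divergence-conforming
basis functions. The 4-source (Whitney) stencil uses the four face
functions of the containing element, each supported on the element and its
face neighbor, $w_F = (x-p_{\text{opp}})/(3V)$ on each side, with dipole
moment $(q - p)/4$ (the segment between the two opposite vertices). The
10-source stencil adds the six edge functions
$w_{ab}=\lambda_a\nabla\lambda_b-\lambda_b\nabla\lambda_a$ of the element.
All integrands against nodal gradients are (piecewise) linear, so load
vectors are exact one-point formulas and every load is exactly zero-sum
(compatible with the pure-Neumann operator). The stencil adapts to the
source compartment: face functions whose neighbor element leaves the active
compartment are dropped (10-stencil) or restricted to the single element
and flagged (4-stencil, mesh boundary).

Position-based optimization (PBO) combines the stencil into a dipole with a
requested moment at a requested position by the weighted
minimum-norm problem

$$\min \sum_k d_k^2 c_k^2\quad\text{s.t.}\quad\sum_k c_k m_k = m,$$

with $d_k = \lVert p_k-\text{pos}\rVert + 10^{-3}h$ ($h$ = local element
size). The constraint is enforced exactly (residuals ~1e-15); the distance
weighting concentrates the coefficients near the requested position, and
the small relative floor keeps the weights finite when a basis function is
centred exactly on the source. The raw Whitney mode bypasses interpolation
entirely and exposes one column per mesh-based face function.

On a homogeneous sphere at resolution `h = r/10` the FEM potentials match
the analytic dipole-in-sphere series with median RDM ≈ 0.07 and median MAG
≈ 1.0 over random dipoles of eccentricity ≤ 0.7; individual dipoles
unluckily aligned with the voxel grid can reach RDM ~0.15 and MAG ~1.2 at
high eccentricity, which is why accuracy is summarized by distribution
medians (the usual practice for forward-solver validation). The 10-source
stencil is marginally but consistently more accurate than the 4-source one
under this comparison.

## Linearized EIT

The conductivity Jacobian is assembled by the adjoint method: with drive
field $u_d$ and measurement-adjoint field $u_m$ (both obtained from one
transfer solve per electrode),

$$J[(d,m),e] = -\int_e \nabla u_d\cdot\nabla u_m\,dV
             = -V_e\,(\nabla u_d\cdot\nabla u_m)_e ,$$

exact for linear elements. Element columns are aggregated onto conductivity
DOFs by nearest-DOF-center assignment, restricted to the designated
(default: active) compartments. Finite-difference checks against nonlinear
re-solves agree to ~1e-4 relative at $\delta\sigma=10^{-4}$ S/m — the
residual is dominated by genuine second-order FD truncation
($\delta\sigma/\sigma\approx 3\times10^{-4}$). The default injection
protocol pairs every electrode against a fixed reference with unit current
(E−1 patterns of full rank); measurements are zero-mean electrode voltages
per pattern.

## Hierarchical Bayesian inversion

The observation model is $y = Lx + n$ with independent Gaussian noise of
standard deviation $\sigma_n$, usually set as a percentage of the largest
data entry (3% for the EEG studies, 12% for EIT). The prior is
conditionally Gaussian with per-location variances $\theta_i$ carrying a
gamma (G) or inverse-gamma (IG) hyperprior with shape $\beta$ and scale
$\theta_0$; the reciprocal of a G variable with scale $\theta_0$ is IG with
scale $1/\theta_0$, which couples the two hypermodels.

**IAS.** Each iteration alternates two exact conditional maximizers:

* x-step (data-space form, inverting only an $n_{\text{sensors}}$-square
  matrix): $x = D L^\top (L D L^\top + \sigma_n^2 I)^{-1} y$,
  $D=\mathrm{diag}(\theta)$, solved by Cholesky (the data-space matrix is
  SPD but can be extremely ill-conditioned when $\theta_0\gg\sigma_n^2$;
  Cholesky handles this where a generic solve refuses);
* θ-step, per location with $s_i=\lVert x_i\rVert^2$ over its $k$
  components and $\eta=\beta-(k+2)/2$:
  G: $\theta_i=\theta_0\big(\eta/2+\sqrt{\eta^2/4+s_i/(2\theta_0)}\big)$;
  IG: $\theta_i=(\theta_0+s_i/2)/(\beta+(k+2)/2)$,
  floored at $10^{-12}\theta_0$ so variances stay positive.

Unconstrained sources share one $\theta$ across their three Cartesian
components ($k=3$); normally constrained sources and EIT DOFs use $k=1$.
The step count convention: `n_ias_steps` counts θ-updates, each preceded
and followed by an x-update; `n_ias_steps = 0` returns the single x-step at
$\theta=\theta_0$. Coordinate descent on the exact conditionals makes the
negative log posterior non-increasing, which the tests assert. The ROI
variant runs the identical scheme on the column-restricted lead field and
returns exact zeros off-ROI.

**Multiresolution averaging.** For EIT the DOF set is decomposed into
randomly centred nearest-point subsets; subset lead-field columns are
summed, the IAS MAP computed on the reduced problem and broadcast back, and
the final estimate is the mean over many randomized decompositions.
Decompositions are chained serially: the previous full-resolution estimate,
projected by subset means, initializes the next decomposition's variances.
Empty subsets are repaired by redrawing only the empty centers;
`n_subsets = n_DOFs` is treated as the exact finest resolution (identity
partition), which also makes a single-decomposition run coincide with the
plain IAS MAP.

**Gibbs sampler.** The conditional mean alternates an exact Gaussian draw
of $x\mid\theta,y$ (perturbation form using the same data-space solve:
$x=\tilde x+DL^\top(LDL^\top+\sigma^2I)^{-1}(y-L\tilde x-\tilde n)$ with
$\tilde x\sim N(0,D)$, $\tilde n\sim N(0,\sigma^2 I)$) and the conjugate
variance draw: IG hypermodel →
$\theta_i\mid x_i \sim \mathrm{IG}(\beta+k/2,\ \theta_0+s_i/2)$; G
hypermodel → a generalized inverse-Gaussian conditional, drawn with a
shifted ratio-of-uniforms sampler written for this package (bounds located
numerically per draw; the gamma and inverse-gamma limits are handled in
closed form). On a 1-DOF model the sampled conditional mean matches a
two-dimensional quadrature of the exact posterior within Monte-Carlo error
(batch-means standard errors).

## Study conditions and units

The synthetic studies reproduce the published experimental designs at desk
scale; the sizes below are the package's own choices and are asserted by
the test suite.

* **EEG hyperparameter study** (`hyperparameter_experiment()`): three-layer
  concentric-sphere head (radii 92/85/80 mm; conductivities 0.43, 0.0064,
  0.33 S/m), 8 mm mesh (~70k elements), 32 disc electrodes, 1200
  uniformly placed unconstrained sources, a simultaneously active deep
  (25 mm) and superficial (68 mm) 10 nAm dipole pair, 2% relative Gaussian
  noise, 50 noise realizations, two IAS steps, ROI-restricted IAS over
  30 mm ROIs, cases $\{G, IG\}\times\theta_0\in\{10^{-5},10^{-9}\}$ at
  $\beta=1.5$. **Units:** amplitudes are measured in nAm and lead-field
  columns in V/nAm. This is a deliberate convention: the hyperprior scale
  grid only differentiates the two hypermodels when the coefficient scale
  is commensurate with $\theta_0$ — with coefficients in A·m
  ($s\sim10^{-16}$) both hypermodels collapse onto fixed minimum-norm
  priors and the G/IG comparison becomes vacuous. Under this convention
  the superficial source is localized within one element diameter in
  effectively all realizations and, at the study's fixed geometry, IG beats
  G on the deep ROI in ≥95% of noise realizations while G remains
  comparable superficially at $\theta_0=10^{-5}$ — the qualitative
  ordering the method is known for. A caveat the desk scale makes visible:
  the experiment (like its published counterpart) fixes one geometry and
  one source cloud and replicates only the noise, and within a cloud the
  two hypermodels' ROI centers of mass are nearly deterministic. Across
  independently re-drawn source clouds the deep ordering flips in roughly
  half the cases at this resolution — with ~7 DOFs per 30 mm ROI the
  discrete cloud geometry contributes as much to the center-of-mass error
  as the hypermodel does. The ordering should therefore be read as a
  property of the replicated design, not of arbitrary coarse source
  spaces.
* **EIT hemorrhage study**: same three-layer phantom at 12 mm resolution,
  16 disc electrodes (24 mm diameter, 1 kΩ), a 30 mm spherical anomaly of
  +0.73 S/m inside the brain compartment, 60 dB SNR difference data, 12%
  likelihood standard deviation, IG with $\beta=1.5$, $\theta_0=0.001$,
  two IAS steps, 800 conductivity DOFs, 20 randomized decompositions of
  100 subsets. Averaging the decomposition estimates narrows the
  center-of-mass error spread (≈6.0–6.9 mm versus 3.8–9.6 mm for single
  decompositions) and improves the median (≈6.2 vs ≈7.1 mm); the
  per-seed probability that the average beats a single decomposition is
  ≈0.7, so the seed-wise comparison in the tests sits close to its
  threshold by nature, not by accident.

## What the synthetic phantoms do and do not show

The layered icosphere segmentations exercise every code path the real
pipeline uses — nested and intersecting closed surfaces, compartment
priorities, conductivity contrasts, CEM electrodes, uniform source clouds —
and admit an analytic oracle (the classical spherical-harmonic series for a
dipole in a homogeneous conducting sphere, truncated at machine tolerance,
which reduces to $3(m\cdot\hat r)/(4\pi\sigma R^2)$ for a central dipole).
They do not reproduce the geometric complexity of real heads: cortical
folding, thin and locally open CSF layers, anisotropic white matter, or
realistic electrode placement. Passing the phantom suite therefore
validates the numerics (assembly, solvers, source models, inverse algebra)
and the qualitative behaviour of the estimators, not clinical localization
accuracy. Real-data ingestion is limited to the file formats: FreeSurfer
ASCII surfaces, node/triangle pairs, INI segmentations, delimited
parcellations and measurement matrices.

## Degenerate inputs and tie-breaking

* Zero-volume elements abort assembly naming the element; negative
  orientations are repaired at mesh generation.
* Nearest-point assignments (EIT DOFs, decompositions, parcellation
  labels) break distance ties toward the lowest index / region id.
* Parcellation DOFs farther than the 10 mm cap from any labeled point stay
  unassigned; all-unassigned inputs warn.
* Correlations of constant region time series are reported as 0 and
  flagged instead of NaN.
* An all-zero measurement vector is rejected when deriving the likelihood
  standard deviation.
* The default tissue conductivity table (white 0.14, grey 0.33, skull
  0.0064, scalp 0.43 S/m) does not include a printed CSF value in its
  source; the package uses the standard literature value 1.79 S/m and the
  table is overridable per compartment.

## Known limitations

* Linear tetrahedral basis only; no adaptive or graded meshing.
* The bi-Laplacian smoother shrinks closed convex boundaries slightly;
  do not smooth before convergence studies against analytic geometries.
* The annulus-membership electrode model needs boundary faces smaller than
  the ring width; coarse studies must use disc electrodes.
* MEG is out of scope, as are non-diagonal prior covariances.
* The multiresolution average inherits a small centroid-ward bias from the
  positive-part center-of-mass summary on coarse DOF clouds.
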