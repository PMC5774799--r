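---
title: "Modelling task fMRI as a susceptibility perturbation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling task fMRI as a susceptibility perturbation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldpert)
```

## The model

`boldpert` treats a task fMRI experiment as a pair of linear(isable) maps
acting on a magnetic susceptibility source and its inverse. The source is
decomposed additively,

$$\chi(\mathbf r, t) = \chi_0(\mathbf r) + \delta\chi(\mathbf r, t),
\qquad |\delta\chi| \ll |\chi_0|,$$

with a static tissue background $\chi_0$ (order $\pm 0.5$ ppm, bipolar:
ferritin/deoxyhaemoglobin-like structures positive, water-like tissue
negative) and a weak task-locked BOLD perturbation $\delta\chi$ (order
$\pm 0.03$ ppm). Three stages connect the source to the data:

1. **Magnetisation / dipole field.** Linear magnetisation in the main field
   gives $b = B_0\,(\chi\times 10^{-6}) \circledast h$ with the point-dipole
   kernel $h(\mathbf r) = (3z^2 - r^2)/(4\pi r^5)$, computed in Fourier
   space as multiplication by $D(\mathbf k) = 1/3 - k_z^2/|\mathbf k|^2$.
   Because the additive decomposition commutes with convolution, the field
   splits identically: $b = b_0 + \delta b$.
2. **Intravoxel dephasing.** A gradient-echo voxel signal is the normalised
   average of unit phasors over the voxel,
   $C[\mathbf r] = |\Omega|^{-1}\sum_{\mathbf r' \in \Omega} e^{i\gamma T_E
   b(\mathbf r')}$, so $C = 1$ at $T_E = 0$ and $|C| \le 1$ always, with
   equality exactly when the intravoxel field is constant. Magnitude is a
   quadratic (sign-destroying, hence non-invertible) function of the field;
   phase is linear to first order, $P \approx \gamma T_E b$ — which is why
   only the phase pathway supports source reconstruction.
3. **Phase perturbation.** With $P = P_0 + \delta P$, complex division
   against a reference frame, $\delta P = \mathrm{Arg}\,(e^{iP}/e^{iP_\mathrm{ref}})$,
   removes the (arbitrarily heavily wrapped) static background exactly and
   returns the true change whenever it lies in $(-\pi, \pi)$ — temporal
   unwrapping for free. The full-$\chi$ pathway instead needs spatial
   unwrapping of each volume, done with the Fourier Laplacian operator,
   which also annihilates harmonic background phase.

The inverse pipeline runs these maps backwards: phase $\to$ field
(division by $\gamma T_E$) $\to$ susceptibility (dipole inversion). Both
$B_0$ and $T_E$ cancel between forward and inverse, so reconstructed
$\chi$ is expressed directly in ppm.

## Dipole inversion

The dipole kernel vanishes on the magic-angle cone, so inversion is
ill-posed. Two standard regularisations are implemented:

* **TKD** (truncated k-space division): $\hat\chi(\mathbf k) =
  \hat b(\mathbf k) / (B_0 D(\mathbf k))$ where $|D| \ge$ `tkd_threshold`
  (default 0.1), zero in the cone. Linear, exact on passband-limited
  spectra, but cone content is lost — a uniform sphere's interior mean
  comes back low by roughly 15%.
* **TVB** (total-variation split-Bregman): approximately minimises
  $\|D\hat\chi - \hat b\|_2^2 + \lambda\,\mathrm{TV}(\chi)$ by alternating
  an exact Fourier-domain quadratic solve (multiplication by $D$, never
  division), isotropic soft-threshold shrinkage of the forward-difference
  gradient field, and a Bregman update. The TV prior fills in the cone
  with a piecewise-smooth extrapolation; on the noiseless demo sphere the
  interior mean is recovered to about 2%.

Defaults: `tv_weight` $\lambda = 2\times10^{-3}$ relative to a field
normalised to unit maximum (the normalisation makes $\lambda$ scale-free;
the result is rescaled afterwards), `bregman_penalty` $\mu = 10\lambda$,
at most 100 iterations, relative-change stopping tolerance $10^{-4}$,
TKD warm start. These are conventional QSM-range engineering choices, all
exposed in `inversion_config()`. Iterations that hit `max_iters` return
the current iterate with `converged = FALSE` (and one message per series),
never an error. The split-Bregman residual is not strictly monotone; in
practice per-step increases stay well under 1%, and the tests bound them
at 2%.

The inversion FFTs run unpadded by default (`zero_pad = FALSE`), keeping
the operator exactly diagonal in Fourier space — this is what makes the
TKD passband identity exact and the operator linear to machine precision.
The forward simulation pads 2× per axis by default to suppress periodic
wrap-around of the dipole tails; the residual forward/inverse boundary
mismatch is part of the round-trip error budget and stays within the
tested bounds for centred compact sources.

## The phantom: what it emulates, what it does not

`demo_phantom_spec()` fixes the study conditions used throughout the tests:

* 64³ voxels at 1 mm (tests that only need geometry scale down to 16–48³);
* an ellipsoidal "brain" envelope (+0.05 ppm baseline) containing four
  static spheres at −0.5 to +0.5 ppm — a bipolar background spanning the
  tissue susceptibility range;
* two task-locked spheres of +0.02 and −0.02 ppm (bidirectional BOLD
  response, $|\delta\chi| \le 0.03$ ppm, an order of magnitude below the
  background so the perturbation premise is testable:
  $\max|\delta\chi|/\max|\chi_0| \le 0.1$);
* a 7T-style block paradigm — 5 cycles of 5 ON / 5 OFF volumes at
  $T_R = 3$ s, 50 volumes — with a 165-volume 3T-style design
  (5 × {15 OFF, 15 ON} + 15 OFF) exercised in the paradigm tests;
* acquisition $B_0 = 7$ T, $T_E = 29$ ms, $\gamma = 2.6752218744\times10^8$
  rad s⁻¹ T⁻¹ (the proton value; the model only ever uses the product
  $\gamma T_E B_0$).

The temporal shape of $\delta\chi$ is `amplitude × task*`, with
`task*` the boxcar convolved with a canonical double-gamma HRF (peak delay
6 s, undershoot delay 16 s, unit dispersions, peak:undershoot 6, 32 s
kernel, peak-normalised). This linear neurovascular response is a modelling
choice, not a physiological claim — it makes correlation recovery
analytically predictable. The convolution is computed directly (not by
FFT) so the regressor is exactly zero before the first ON block; the small
post-block undershoot is rectified so `task*` stays in $[0, 1]$, matching
the ON-state convention `task* >= 0.5`. ON/OFF classification thresholds at
0.5 *after* peak normalisation.

Two noise entry points exist, both off by default and both seeded:
Gaussian source noise added to $\delta\chi$ (ppm), used to set detection
difficulty (amplitude/σ = CNR ≈ 5 in the functional-mapping tests), and
complex Gaussian noise added to the T2* data, the analogue of thermal
measurement noise. The distinction matters: source noise is genuine signal
in the field and is faithfully reconstructed, whereas measurement noise is
what TV regularisation suppresses — the "reconstruction is smoother than
the phase" property is therefore asserted under measurement noise, where
it holds (TV 6.3 vs 10.4 in common ppm units on the 32³ demo), and not
under source noise, where no inversion could or should smooth it away.

What the phantom does **not** emulate: vascular geometry (spheres, not
vessel trees), partial-volume tissue mixtures, physiological fluctuations
(cardiac/respiratory), scanner drift, coil sensitivity and combination
effects, EPI distortion, or relaxation weighting. Passing tests therefore
demonstrate the correctness of the transform chain under its stated
assumptions, not performance on in vivo data.

## Numerical choices

* **Frequency grids.** All operators share one convention: physical
  frequencies $k_i = \mathrm{idx}_i/(n_i d_i)$ cycles/mm (anisotropic
  voxels handled naturally). The Laplacian unwrapper's $k^2$ uses the same
  grid; any isotropic rescale cancels between numerator and denominator
  (tested). Its $k = 0$ coefficient is set to 0 — forced by the formula —
  so unwrapped output is mean-free.
* **Mean-free fields.** $D(0) = 0$ by convention: the uniform-$\chi$ field
  offset is unobservable in phase differences. Field maps are re-centred
  after any cropping so the convention survives padding.
* **Discretisation.** A single-voxel delta is a poor discretisation of the
  dipole kernel at short range (~2× error a few voxels out), though smooth
  sources converge — the analytic-sphere oracle agrees to 0.5% RMSE. For
  oracle work, spheres are rasterised with centred subvoxel partial-volume
  fractions (`rasterize_sphere()`), which suppresses surface Gibbs ringing;
  phantom blobs remain binary by design (piecewise-constant contract).
* **Supersampled dephasing.** Intravoxel averaging uses `supersample`
  field samples per axis per voxel (nearest-neighbour upsampling of the
  piecewise-constant source, centred block averaging of phasors). The
  demo simulations run at `supersample = 1`, where phase is exactly
  $\gamma T_E b$ wrapped — the regime the linear inverse assumes; the
  dephasing tests exercise factors 2–4.
* **Degenerate inputs.** Constant voxel timecourses get $r = 0$, $p = 1$,
  $z = 0$ (air/background convention). $|r| = 1$ underflows $p$ to the
  smallest positive double; $r$ is clamped infinitesimally inside
  $(-1, 1)$ before the Fisher transform so $z$ stays finite. Zero-spread
  inactive ROIs flag their frame and drop it from SNR/CNR averages with a
  warning. The complex-division reference frame is identically zero and is
  excluded from metric time averages by the $N_t - 1$ convention when
  `exclude_index` is set.
* **No multiple-comparison correction** is applied to the p-maps; they are
  raw voxel-wise statistics, and thresholded displays should be read
  accordingly.

## Design decisions that were genuinely open

* The correlation estimator is Pearson (the $[-1, 1]$ range convention and
  regression context imply it); significance uses the exact t-transform
  and Fisher z — standard, and isolated in `tcorr_significance()` so they
  can be swapped.
* The reference frame for complex division defaults to frame 1 but is
  configurable — any frame works, and metrics exclude whichever was used.
* No brain-mask weighting is applied anywhere by default; the unwrapper
  accepts an optional mask.
* Oblique $B_0$ is supported through the $k_z$ projection of a unit
  `b0_direction` vector; the default is the third array axis.
* The full-$\chi$ pathway reports mean-free relative susceptibility only
  (no tissue-baseline referencing): the DC component is unobservable.
* Problem sizes in tests and the acceptance script (16³–64³, 1–50 frames)
  were chosen as the smallest grids on which each property is
  numerically meaningful — e.g. 64³ for oracle comparisons so the sphere
  has both a resolved interior and a decaying exterior.

## Known limitations

* TVB convergence at the default tolerance typically requires more than
  the default 100 iterations on structured noiseless fields; results are
  accurate well before formal convergence (the tests pass with the flag
  false), but the flag should be checked when parameters change.
* The Laplacian unwrapper assumes effectively periodic inputs; phase
  structure running into the boundary leaks. Real data should be roughly
  centred in the FOV, as the phantom is.
* TKD linearity is exact; TVB is mildly non-linear through its
  regulariser, so perturbation additivity holds only approximately there
  (tested only for TKD).
* Performance: everything is plain-R FFT work; a 64³ frame costs ~0.5 s
  forward and ~0.05 s (TKD) to ~4 s (TVB) inverse. Whole-brain matrices
  at EPI resolution are feasible but slow; the design favours clarity and
  testability.
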