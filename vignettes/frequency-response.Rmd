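---
title: "Frequency-response analysis of periodically perturbed protein dynamics"
author: "freqresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-response analysis of periodically perturbed protein dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqresp)
```

## The idea

When a small region of a protein is driven periodically between two
conformations — for example by a targeted-dynamics restraint that
alternates its target structure every half-period — the perturbation
propagates through backbone connectivity and nonbonded contacts. Every
atomic variable that receives the signal (a Cartesian coordinate of a
C-alpha atom, a backbone or side-chain dihedral angle, a polar-contact
distance) acquires excess spectral power at the forcing frequency
$f_b$ and its harmonics, superimposed on the $1/f$-like background of
thermal fluctuations. Working in the frequency domain turns a weak,
noise-clouded response into a sharp, testable feature: a single spectral
ordinate compared against a fitted power-law baseline.

`freqresp` implements the full chain: spectral estimation, statistical
detection, phase clustering, collective-displacement summaries, and
lead-lag (Bode) characterization, together with synthetic generators
that reproduce the statistical structure of the problem at desk scale.

## Spectral estimation

For a series $x_n$, $n = 0,\dots,N-1$ sampled every $dt$ ps, the DFT is
$X_k = \sum_n x_n e^{-2\pi i kn/N}$ (no forward normalization). After
mean-centering, the one-sided spectral density assigns component $k$
the mean-square-fluctuation (MSF) contribution

$$P_k = \frac{2|X_k|^2}{N^2}, \qquad 0 < k < N/2,$$

with the Nyquist term (even $N$) appearing once. Parseval's relation
then guarantees $\sum_k P_k = \mathrm{MSF}$ exactly, which the test
suite asserts to $10^{-9}$ relative. Frequencies are reported in
ns$^{-1}$: $f_k = k/(N\,dt) \times 1000$.

No windowing or detrending is applied. The pipeline therefore requires
the forcing period to divide the trajectory duration, so $f_b$ falls
exactly on a DFT bin; off-bin configurations are rejected up front
rather than silently leaking power across bins.

Band reconstruction keeps one component (and its conjugate) and
inverts, which is analytically the sinusoid
$r_n = a\cos(2\pi kn/N + \phi)$ with $a = 2|X_k|/N$,
$\phi = \mathrm{Arg}(X_k)$. All downstream phases use this cosine
convention.

Dihedral-like variables are circular: each angle series is embedded on
the unit circle as mean-centered $(\cos\theta_n, \sin\theta_n)$
components and the two component densities are summed. This avoids
branch-cut artifacts from rotamer jumps while preserving the spectral
location of planted oscillations.

## Detecting perturbed variables

Protein fluctuation spectra empirically follow $P(f) \sim 1/f^\beta$
over a wide band, a straight line on log-log axes. The detector fits
ordinary least squares of $\log_{10} P_k$ on $\log_{10} f_k$ and flags
a variable when its power at $f_b$ exceeds a one-sided upper Student-t
limit about the line:

$$L = \hat y(x_0) + t_{1-\alpha,\,n-2}\; s\,
  \sqrt{1 + \tfrac1n + \tfrac{(x_0-\bar x)^2}{S_{xx}}}.$$

Defaults, all configurable: the first 10 components are excluded (slow
diffusive motion inflates them above the power law), the fit stops at
6 ns$^{-1}$ (above which the power law degrades at 1 ps sampling), and
the forcing component plus its first three harmonics are excluded so
the tested point cannot inflate its own baseline. Significance levels
default to $\alpha \in \{0.05, 0.01\}$.

Two genuinely open choices deserve comment.

**Prediction vs confidence limit.** The question asked is whether a
single new spectral ordinate exceeds the line, so the default includes
the "+1" term (prediction limit); `interval = "confidence"` switches to
the mean-response variant, which is tighter and flags more.

**Calibration is conservative, by distribution theory.** For Gaussian
noise the periodogram ordinates are exponentially distributed, so the
log-spectrum scatters with a left-skewed (log-exponential)
distribution whose right tail is *lighter* than the normal tail the
t-limit assumes. The package's own calibration experiment (2000 seeded
pure-$1/f$ trajectories, $N = 16000$, tested at $k = 32$; run by
`scripts/acceptance.R` and the acceptance test suite) measures an
empirical false-positive rate of about 0.013–0.017 at nominal
$\alpha = 0.05$. The test is therefore *valid* (it never exceeds its
nominal level — the property the unit suite asserts) but not *exact*:
flagged variables are, if anything, under-reported. A nominal-level
match cannot be obtained from any faithful spectral-synthesis
generator: deterministic spectral amplitudes make the residual scatter
degenerate ($s \to 0$), and stochastic amplitudes give the skewed
ordinates just described. We consider the conservative behavior the
scientifically honest operating point and document it rather than
recalibrating the limit to force a match.

## Phase clustering

Two variables oscillating at $f_b$ move concertedly only if their
phases agree — but for dihedral-like variables a phase difference of
$\pi$ is indistinguishable from a sign convention, so raw phases are
folded to $[0, \pi)$ and embedded on the doubled-angle plane
$(\cos 2\theta, \sin 2\theta)$, where one turn corresponds to a phase
difference of $\pi$. The folded separation
$\min(|\Delta|, \pi - |\Delta|)$ is a proper metric; e.g. phases
$\pi/12$ and $11\pi/12$ are only $\pi/6$ apart.

A multi-component variable (the x/y/z coordinates of one atom; the
cos/sin branches of a dihedral) gets a single phase from the first
principal direction of its band-reconstructed components — the
projected score is again an on-bin sinusoid whose phase is read off
its DFT. The phase reference is the forcing schedule's fundamental DFT
phase; only relative separations are physically meaningful.

Clustering defaults to four half-open bins of width $\pi/4$
(`quadrant_cluster`), with seeded k-means on the embedding as an
alternative; k-means labels are renumbered by ascending circular-mean
phase so results are deterministic. Distance variables are refused by
default: the difference of two nearly equal-amplitude, nearly in-phase
signals has a phase near $\pi/2$ away from its constituents (the test
suite reproduces this construction), so clustering them alongside
coordinates would mislead.

## Collective displacements

PCA of the band-reconstructed coordinate matrix condenses the forced
motion into one eigenvector $p$; the score along $p$ is fitted as
$a_s \cos(\omega t + \phi)$ and the per-atom predicted displacement is
**peak-to-peak**, $R_i = 2 a_s \|p_i\|$, because the experimental
reference is the full displacement between two end conformations, not
an amplitude about the mean. The sign of $p$ is chosen so the
collective motion is in-phase with the forcing. Comparisons with an
experimental displacement field $d$ use the absolute cosine overlap
$|p \cdot d|/(\|p\|\|d\|)$ (direction), the projection-norm subspace
overlap $\|P_m P_m^T d\|/\|d\|$ for the best linear combination of $m$
eigenvectors, and the Pearson correlation of $R_i$ with $D_i$
(amplitude pattern). Covariance (not correlation) PCA is used, with
variables in Angstrom; near-degenerate leading eigenvalues trigger a
warning since the first eigenvector is then ill-determined.

## Lead-lag (Bode) characterization

Across forcing frequencies, a variable's amplitude ratio
$AR(\omega) = a(\omega)/A_{\mathrm{forcing}}$ is modeled by the
single-state, stable, minimum-phase lead-lag system

$$G(s) = K_p\,\frac{\tau_z s + 1}{\tau_p s + 1}, \qquad
AR(\omega) = K_p\sqrt{\frac{(\tau_z\omega)^2 + 1}
                           {(\tau_p\omega)^2 + 1}},$$

fitted on the 20-log10 dB scale (which balances octaves) by
deterministic multi-start bounded quasi-Newton optimization over
log-parameters, with time constants bounded to $[10^{-3}, 10^4]$ ps.
The unit-step response
$y(t) = K_p(1 - (1 - \tau_z/\tau_p)e^{-t/\tau_p})$ makes the physical
reading direct: a fraction $\tau_z/\tau_p$ of the final displacement
appears immediately, the rest relaxes with time constant $\tau_p$, and
$\tau_z > \tau_p$ means overshoot then partial return — the signature
seen in flexible loops whose net displacement is small although they
move during the transition. The breakpoint $\omega_c = 1/\tau_p$
separates transmitted from attenuated forcing; $\tau_p = 200$ ps gives
$\omega_c = 5$ rad/ns ($f_c \approx 0.8$ ns$^{-1}$).

Responses are classified as lead-lag (fit $R^2 \ge 0.8$; lag- or
lead-dominant by the $\tau$ ordering), `monotone_unfit` (Spearman
$|\rho| \ge 0.8$ but no acceptable single-state fit), or
`second_order_or_none` (interior humps, flat, or trendless). The 0.8
thresholds are package choices; the underlying study reported a
fraction "well represented" without stating a criterion. The default
Bode design is 13 periods log-spaced from 30 ps to 5 ns — the stated
endpoints and count, with log spacing our interpolation.

## Synthetic data: what it emulates and what it does not

**Power-law noise.** `pink_noise()` synthesizes $1/f^\beta$ series in
the spectral domain. The default draws complex-Gaussian coefficients
with $E|X_k|^2 \propto k^{-\beta}$ — the standard construction for
Gaussian power-law noise, whose periodogram scatters about the power
law as real spectra do. An `amplitudes = "fixed"` mode (deterministic
magnitudes, random phases) gives an exactly linear log-log spectrum for
analytic checks. The realized MSF is rescaled exactly to the requested
value, and planted on-bin sinusoids are added afterwards, so planted
amplitude and phase round-trip exactly through `band_reconstruct()`.

**Circular variables.** `synth_circular()` superimposes Gaussian
angular noise, Poisson-timed jumps between rotamer targets (which
inflate the lowest frequency components, as side-chain rotamer
transitions do), and optional planted oscillations.

**The toy driven network.** `toy_tmd_simulate()` integrates overdamped
(Brownian) Euler–Maruyama dynamics on a harmonic contact network built
over a deterministic compact helical chain (60 beads, 3.8 Å virtual
bonds, contacts within 8 Å, 331 springs with native rest lengths). The
driven subset (beads 28–33, a contiguous "loop") feels a per-bead
harmonic pull toward a target interpolated between conformations A
(reference) and B (the loop displaced 3 Å radially) along a symmetric
triangle schedule — the waveform implied by a linearly ramped target
RMSD; a square-target option exists for studying harmonic content.
The per-bead pull is a deliberate simplification of a holonomic
RMSD-ramp restraint: it preserves the forcing's spectral structure,
which is what the analysis consumes. Constants were chosen from the
network's reference Hessian spectrum: $k_{\mathrm{net}} = 2$
kcal/mol/Å$^2$ and $\gamma = 20$ kcal mol$^{-1}$ Å$^{-2}$ ps put the
slowest network relaxation at 262 ps (a few hundred ps, the regime in
which ns-period forcing transmits and tens-of-ps forcing attenuates)
and the fastest near 1 ps; the 0.5 ps integration step is half the
Euler stability limit computed from the exact top Hessian eigenvalue,
and $kT = 0.593$ kcal/mol corresponds to 300 K. Inertia is omitted
deliberately: the analyzed band (below a few ns$^{-1}$) is far below
any inertial timescale of a solvated protein.

What passing tests on these generators do **not** show: real proteins
are anharmonic, their noise is neither Gaussian nor exactly power-law,
solvent damping is frequency-dependent, and real restraints act on
collective RMSD rather than per-bead positions. The generators
establish that the *statistical machinery* is correct and calibrated
under its stated assumptions — not that any particular protein behaves
like the toy network.

## Numerical choices and degenerate inputs

* Superposition uses the Kabsch algorithm with uniform weights
  (reflections excluded); selections with fewer than 3 non-collinear
  atoms are rejected as underdetermined.
* Torsions follow the IUPAC convention (cis = 0, right-handed
  positive), folded to $(-180, 180]$ degrees; collinear triples raise
  an error naming the offending frame.
* Constant series are valid spectral inputs (zero density) but
  degenerate detection inputs; `scan_variables()` records the error
  per variable and completes.
* A zero-amplitude band reconstruction reports an undefined-phase
  marker (`NA`) rather than an arbitrary angle.
* Polar-contact enumeration (the source protocol is unspecified):
  N/O heavy-atom pairs from distinct residues, 3.5 Å cutoff, 50%
  occupancy, excluding peptide-bond backbone N–O neighbors; an
  explicit pair list can be supplied instead.
* Quadrant bins are half-open, $[(j-1)\pi/4,\, j\pi/4)$; cluster
  numbering ascends with phase. The absolute plot orientation of the
  original analysis is unrecoverable, so only relative separations are
  compared anywhere in the package.
* Equipartition holds on a single bond to within the Euler–Maruyama
  discretization bias (about 3% low at dt = 0.25 ps); the test
  tolerance reflects this.

## Problem sizes

The shipped experiments use: 100 seeded trajectories of $N = 80000$
(dt = 1 ps) for slope recovery; 2000 of $N = 16000$ for type-I
calibration; one 80 ns toy-network run (80000 frames, 60 beads) for
the forced-peak check; 20-seed recovery experiments at $N = 2048$ for
collective displacement and lead-lag noise robustness. These sizes
give Monte-Carlo standard errors comfortably below the tolerances they
are compared against.

## Known limitations

* No windowing means strictly on-bin forcing; analyzing externally
  produced trajectories whose forcing period does not divide the
  length requires truncation to a whole number of cycles.
* The detector controls the per-variable level only; dependence
  between variables (e.g. x/y/z of one atom) is not modeled, and
  multiple testing is left to the optional Benjamini–Hochberg column.
* The calibration gap discussed above means reported flag counts are
  conservative at nominal $\alpha$.
* Binary trajectory formats (DCD/XTC) are out of scope; the readers
  handle multi-model PDB and plain tables, and are the documented
  extension point.
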