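---
title: "Time-optimal multiband RF pulses with realistic gradients: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-optimal multiband RF pulses with realistic gradients: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbverse)
```

## The problem

Simultaneous-multislice (SMS) imaging excites N slices at once with a
multiband (MB) RF pulse. The simplest construction multiplies a singleband
(SB) pulse by a modulation function

$$ f_N(t) = \sum_{n=1}^{N} e^{i(\gamma G t x_n + \phi_n)}, $$

which replicates the slice profile at positions $x_n$. Its peak grows
roughly like $\sqrt{2N}$ even with optimized phase offsets $\phi_n$, so
fixed peak-B1 hardware forces long pulses. Time-optimal VERSE (variable-rate
selective excitation) shortens a pulse by reshaping RF and gradient jointly
along the excitation k-trajectory, preserving the on-resonance profile while
riding the peak-B1, gradient-amplitude and slew-rate limits.

VERSE and MB modulation can be combined in two orders:

* **MBv** — modulate first, then VERSE the multiband pulse. The gradient
  inherits the fast MB amplitude modulation.
* **vMB** — VERSE the singleband pulse under the reduced limit
  $B_{1,\max}/\max_t |f_N^v(t)|$, then modulate with the time-variable form
  $f_N^v(t) = \sum_n e^{i(k(t) x_n + \phi_n)}$, where
  $k(t) = -\gamma \int_t^T G(s)\,ds$. The gradient stays smooth because the
  modulation lives entirely in the RF.

A real gradient chain is a low-pass system. Modelling it as linear
time-invariant, the realized gradient is the demanded one convolved with the
gradient impulse response function (GIRF). An MBv gradient carries energy at
the MB modulation frequency $\gamma G \Delta x$ (tens of kHz for typical
slice gaps), well beyond typical chain bandwidths; the attenuated and
phase-rotated components displace RF energy in k-space periodically, which
excites *ghost slices* at multiples of the slice separation. The vMB
gradient has no such component, which is the central mechanism this package
quantifies: with a synthetic low-pass GIRF, the out-of-FOV profile error of
MBv exceeds that of vMB several-fold, while a perfect chain leaves both
ghost-free (see `girf_distortion_eps()` and the acceptance tests).

## Design pipeline

**SLR design.** Refocusing pulses are designed through the Shinnar-Le Roux
transform. Profile ripples are specified on the refocusing ($\beta^2$)
profile (1% in and out of slice by default) and mapped to $\beta$-filter
ripples with the crushed-spin-echo relations $\delta_1/4$ and
$\sqrt{\delta_2}$. The $\beta$ filter itself is designed by weighted least
squares with Lawson re-weighting (`firls_lawson()`), which converges to
near-equiripple solutions even for the very narrow normalized bands where
classical Parks-McClellan implementations fail silently; a unit test
cross-checks the realized ripples against `signal::remez` on a case both can
solve. Minimum-phase designs factor a lifted magnitude-squared prototype
with the cepstral method; quadratic-phase designs then reflect the
lower-half-plane $\beta$ roots across the unit circle, which preserves
$|\beta|$ and spreads RF energy in time. The SB filter uses 129 taps —
in this parameterization the Parks-McClellan length estimate is met at *any*
tap count, so the choice only sets the time resolution of the design — and
the pulse is then moved to the 2048-sample working grid by exact
band-limited (Fourier) resampling.

**Root-flipped multiband pulses.** The non-linear-phase MB designs build a
multiband $\beta$ filter directly (one passband per slice) and search over
reflections of its passband roots: each flip $r \to 1/\bar r$ preserves
$|\beta(\omega)|$ but re-times when each band deposits its RF, lowering the
peak. Roots come from companion-matrix eigenvalues with Newton polishing
(base R's `polyroot` loses all accuracy at degree ~500), and flipped
polynomials are rebuilt by evaluating the all-pass factors on a DFT grid and
inverse transforming — multiplying monomial factors overflows at these
degrees, while the DFT route reproduces $|\beta|$ to ~1e-14. The flip
pattern is chosen by a genetic algorithm (population 64, 200 generations,
bit-flip mutation $1/n_\text{bits}$, tournament selection, elitism, fixed
seed, early stop after 40 stale generations) over *individual* passband
roots. Restricting flips to conjugate pairs, which keeps the filter real,
was tried first and found to cap the achievable peak reduction well below
what individual flips reach, so individual flips are the default
(`conjugate_pairs` remains available). On a problem small enough to
enumerate (N = 4, 16 passband roots), the GA's best pattern matches the
exhaustive optimum of all 65,536 patterns to 0.4%, so the search budget is
not the limiting factor of these designs.

**Time-optimal VERSE.** The pulse is reparameterized by arc position along
the (monotone) k-trajectory. At matched k the ratio $w = B_1/G$ is invariant,
so the per-position gradient cap is
$\min(G_{\max},\, B_{1,\max}/|w|)$ and the slew limit becomes
$\mathrm{d}(G^2)/\mathrm{d}s \le 2 S_{\max}/\gamma$. Forward-backward
integration of this bound gives the provably minimum-time traversal; a
dynamic-programming oracle on a refined grid agrees within 2% in the tests.
Gradients may start and end at nonzero values; ramps live outside the RF
window and are not counted in the reported durations (both accountings can
be derived from the exported waveforms — the ramp time is
$G(0^+)/S_{\max}$ per side). The output dwell is chosen so the fastest MB
component advances less than $\pi/8$ per sample; the sub-percent
interpolation overshoot of the active B1 constraint is clipped to the limit.
For vMB, the reduced B1 limit depends on the VERSE'd k-trajectory, which
depends on the limit; the fixed point is solved by damped iteration
(damping 0.5, tolerance 1e-3 on peak times limit, at most 20 iterations —
in practice it converges in one step for equidistant slices because the
modulation peak is traversal-invariant).

**PINS and MultiPINS.** PINS undersamples the SB envelope into
$\lceil \mathrm{TBP} \cdot \Delta x / \Delta z \rceil$ hard subpulses played
at zero gradient, interleaved with the shortest triangular (or, when
amplitude-limited, trapezoidal) gradient blips of area $2\pi/(\gamma\,
\Delta x)$ — one k step of the periodic pattern. RF blips are as short as
the B1 ceiling allows, so their durations vary with the local envelope
area; the gradient blip is fixed by the slew limit. For slice packs with an
even number of slices the periodic pattern is shifted by half a separation
(a linear phase across the subpulses) so it lands on the pack positions.
MultiPINS mixes in a VERSE-reshaped MB component
($\mathrm{RF} = M\,\mathrm{RF}_{MB} + (1-M)\,\mathrm{RF}_{PINS}$): the MB
RF rides the gradient blips in proportion to the instantaneous gradient at
matched k (deposited as the exact k-integral over each sample span, which
matters because the blips sweep k quickly), and larger $M$ shrinks the
B1-limited RF blips until the MB component hits the ceiling. The mixing
ratio is scanned in steps of 0.005.

## Evaluation

**Simulation.** The spin-domain (Cayley-Klein) hard-pulse engine applies,
per dwell, the RF rotation followed by free precession; unitarity holds to
1e-9 per position and an independent rotation-matrix integrator agrees to
1e-8. Waveforms are sample-and-hold, so when the per-dwell precession at the
edge of the evaluation window exceeds $\pi/6$ the samples are subdivided —
an exact refinement that converges to the continuous-physics profile.

**Design targets.** Profile errors need a reference. For modulated methods
the reference is the $\beta$ polynomial of the constant-gradient modulated
parent, obtained by forward SLR at a resolution chosen so the outermost band
stays clear of Nyquist and the polynomial's response covers the whole
evaluation window; this captures all large-tip cross-band effects, so the
error isolates what the VERSE machinery (and nothing else) changed. Na&iuml;ve
linear superposition of shifted SB responses is *not* an adequate target at
180&deg;: the resonant band saturates ($|\beta| \to 1$) where superposition
predicts interference dips, the arccos flip map amplifies $\beta$-level
ripple by $1/\sqrt{1-|\beta|^2}$, and the off-resonant sibling bands
Bloch-Siegert-shift the outer slices by tens of microns (all three effects
are demonstrated in the test suite). PINS is evaluated against an exact
k-space chain: RF blips are pure rotations and gradient blips pure
precessions, so the design *is* a hard-pulse SLR chain on the k axis, and
MultiPINS adds the continuous MB deposit over the swept k range.

**Metrics.** Flip-angle profiles $\theta(z) = \arccos(1 - 2|\beta|^2)$ are
compared over the imaging FOV ($\epsilon_\text{inside}$, $|z| \le$ FOV/2)
and the surrounding annulus up to 3x FOV ($\epsilon_\text{outside}$), both
normalized by the RMS of the target inside the FOV so the outside error is
comparable across methods (the target is essentially zero there, so a
region-local normalizer would be undefined). The spatial grid places 16
points per slice thickness; the profile-error values move by well under 2%
when the density is doubled from 24 points (at 16 the residual is grid
sampling noise of comparable size). Through-slice phase deviation is
quantified on pulses rescaled to a 45 degree peak flip, with the best-fit
linear-in-z phase common to all slices removed (such rolls are refocusable
by rewinders). Off-resonance behaviour reports the outer-slice spatial shift
(maximal cross-correlation with sub-sample parabolic refinement) and the
shift-corrected NRMSE over 0..200 Hz.

## The synthetic GIRF

Measured gradient chains show a low-pass magnitude with an approximately
linear phase (a constant group delay). `make_synthetic_girf()` emulates
exactly that: a Gaussian (or Butterworth) magnitude with a chosen FWHM and a
constant delay. The package default for studies is FWHM 12 kHz with a 2 us
delay — representative of whole-body gradient chains, chosen once before
any acceptance evaluation and not revisited; the qualitative MBv-vs-vMB
separation is insensitive to the exact value because the MBv gradient
modulation sits at $\gamma G \Delta x \approx$ 25-50 kHz for these
geometries, far above any plausible chain bandwidth. What the synthetic
model does *not* emulate: mechanical resonance dips in the magnitude,
frequency-dependent (non-constant) group delay, axis coupling, and
amplitude-dependent (non-LTI) effects. Passing tests therefore demonstrate
the low-pass ghosting mechanism and the machinery around it, not agreement
with any particular scanner.

## Study conditions and problem sizes

The duration comparisons reproduce the reference conditions: 180 degree
refocusing, 2 mm slices, 1% ripples, TBP 4 (TBP 2 in the profile tests),
B1max 13 uT, Gmax 40 mT/m, Smax 200 mT/m/ms, N = 2..12 with a fixed 200 mm
FOV, working waveforms of 2048 samples. The acceptance script runs the
root-flip GA at its full budget; the test suite uses a reduced generation
budget for the same designs (the achieved peaks differ by well under a
percent, see the GA-vs-exhaustive result above) and evaluates the
profile-fidelity matrix at N = 2..4, slice separation 28 mm, TBP in {2, 4}.
Phase-offset optimization uses 64 fixed-seed multistarts plus a polish
stage; the resulting peaks match or slightly improve on the published
optimized values (e.g. $\sqrt 5$ at N = 3), and tables can be persisted as
JSON (`write_phase_table()`). A conjugate-symmetric constraint on the
offsets ($\phi_n = -\phi_{N+1-n}$, making the modulation Hermitian) is
selectable but off by default: the unconstrained optimum is by construction
at least as good, and the tests confirm the constraint never helps.

## Known limitations

* The root-flip search space is the passband-root set of the in-package
  multiband filter. Its global optimum (verified by exhaustive enumeration
  at N = 4) reduces the constant-gradient peak by about 2x relative to the
  phase-optimized linear pulse, which also makes the root-flipped pulses
  flatter — and hence, after VERSE, somewhat *longer* than their linear
  counterparts (a B1-limited time-optimal duration is essentially the
  integral of |RF| over the B1 ceiling). Reports built on other filter/root
  structures can show substantially larger pre-VERSE gaps; with this
  construction the measured mean pre-VERSE linear-vs-non-linear gap and the
  non-linear vMB excess land where the acceptance tests record them, and no
  search budget changes that.
* Relaxation during the pulse, transmit (B1+) inhomogeneity, and
  RF-chain imperfections are out of scope; the GIRF is applied to the slice
  axis only (multi-axis storage is structural).
* Eq-3-convention k-trajectories assume a monotone traversal; RF on a
  zero- or sign-changing gradient segment is rejected rather than handled.
* Durations exclude the gradient ramps outside the RF window; both
  accountings are recoverable from the exported waveforms.
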