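---
title: "Force-controlled cyclic stretching of soft microfibers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-controlled cyclic stretching of soft microfibers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberstretch)
```

`fiberstretch` simulates and analyses a micromanipulation rheometer for
soft hydrogel microfibers: a motorised tube stretches the fiber, a second
compliant tube bends under the transmitted force and doubles as the force
sensor, and a microscope camera reads the sensing tube's tip deflection.
The fiber's elastic modulus is obtained by driving the stretching force
through small sinusoidal cycles under feedback control and reading the
stress–strain ellipse. This vignette records the models, the tunable
parameters and the numerical and design decisions.

## The viscoelastic plant

The fiber is a standard linear solid (SLS): a spring in parallel with a
Maxwell (spring + dashpot) arm. Its stress-relaxation response to a step
displacement $u_0$ is

$$F(t) = (\lambda_1 + \lambda_2 e^{-t/\tau})\,u_0,$$

with $\lambda_1$ the long-time (equilibrium) stiffness in µN/µm,
$\lambda_2$ the decaying excess stiffness and $\tau$ the relaxation time
in s. Two fitted presets ship with the package: `gelma_7pct`
($\lambda_1 = 11.23$, $\lambda_2 = 0.7629$, $\tau = 44.94$) and
`gelma_5p5pct` ($\lambda_1 = 30.72$, $\lambda_2 = 3.584$, $\tau = 56.20$).
The step displacement of the associated relaxation test is taken as
$u_0 = 9$ µm throughout. Note that the 5.5 % w/v preset is the *stiffer*
of the two in these lumped units; the presets are used as-is, since their
role here is to define two distinct plants for the robustness study.

`to_state_space()` realises the displacement-to-force transfer function

$$G(s) = \frac{(\lambda_1+\lambda_2)\,s + \lambda_1/\tau}{s + 1/\tau},$$

as a one-state system (pole $-1/\tau$, feedthrough $\lambda_1+\lambda_2$,
DC gain $\lambda_1$), augmented with the integral tracking state
$e_{yI} = \int (F_f - F_{cmd})\,dt$. Correctness of the realisation is
defined by its step response matching the closed form above — the test
suite asserts agreement to $10^{-6}$ µN over 1000 grid points — not by
any particular matrix layout.

## The adaptive force controller

The control problem is to make the measured stretching force track
$F_{cmd}(t) = A\sin(2\pi f t) + A$ (default $A = 5$ µN, $f = 0.01$ Hz)
despite fiber-to-fiber parameter variation. The controller has three
layers:

1. **Luenberger observer / reference model.** The observer propagates the
   design model under the baseline control and corrects with the measured
   outputs $y = (e_{yI}, F_{meas})$; its state $x_{ro}$ doubles as the
   reference trajectory. Pole placement exploits that $C = I$ here: the
   real Schur form of $A$ has its diagonal replaced by the requested
   poles and $L = (A - A_{des})C^{-1}$, which returns $L = 0$ when the
   requested poles are the plant's own. Defaults place the observer poles
   at $(-20, -30)/\tau$.
2. **LQR baseline.** $u_{bl} = -K_x^\top x_{ro}$ with $K_x$ from the
   continuous Riccati equation, solved by the Hamiltonian stable-subspace
   method. Default weights $Q = \mathrm{diag}(10, 1)$ (weighting the
   force-error integral) and $R = 1$.
3. **Lyapunov adaptive law.** The residual between the
   measurement-reconstructed plant state
   $\bar x = (e_{yI},\, F_{meas} - D u)$ and the reference state drives
   $\dot{\hat\Theta} = -\Gamma\,\Phi\,e_x^\top P (B - LD)$, and
   $u_{ad} = \hat\Theta^\top \Phi(x_{ro})$ augments the baseline.
   $\Phi$ stacks first-kind Chebyshev polynomials (default order 3) of
   the observer states, normalised to $[-1,1]$ by running min/max and
   clamped.

Three design choices here deserve a record, because the architecture is
genuinely open:

* **Which state is fed back.** Feeding back the reconstructed state
  $\bar x$ directly would make the tracking-error dynamics match the
  classical reference-model form, but it injects measurement noise
  straight through the state feedback and degrades tracking beyond the
  1 µN budget. The package feeds back the observer state $x_{ro}$, which
  filters the noise; this is also what makes the method usable when only
  noisy vision is available.
* **Which Lyapunov matrix the law uses.** With observer-state feedback
  the error $e_x = \bar x - x_{ro}$ obeys
  $\dot e_x = (A - LC)e_x + (B - LD)(u_{ad} + f)$, so the decrease
  argument requires $P$ to solve the Lyapunov equation of $A - LC$, not
  of $A_{ref}$. The design therefore carries two certified matrices:
  `P_ref` (certifying $A_{ref}$, the classical object) and `P_err` (used
  by the law). With `P_err` the candidate
  $V = e_x^\top P e_x + \mathrm{tr}(\tilde\Theta^\top\Gamma^{-1}\tilde\Theta)$
  decreases exactly along noise-free matched runs; with `P_ref` it does
  not, and simulations confirm frequent increases.
* **The sign of the law.** With $u_{ad} = +\hat\Theta^\top\Phi$ the
  stabilising gradient step is the *negative* one written above; the
  positive-sign variant closes a positive feedback loop and diverges
  within one loading cycle.

The adaptation rate defaults to $\gamma = 0.001$ ($\Gamma = \gamma I$).
This is deliberately gentle: the matched-uncertainty assumption behind
the law holds only approximately when the true fiber differs from the
design model, so aggressive adaptation ($\gamma \gtrsim 0.1$ here)
amplifies the residual instead of cancelling it and can destabilise the
loop — `run_closed_loop()` detects this and aborts with an `unstable`
condition. At the default, the loop holds the command within
roughly 0.1–0.2 µN on both presets with the controller designed on the
7 % model (the test suite and `scripts/acceptance.R` compute these), and
adaptation does not worsen — and on the mismatched plant slightly
improves — steady-state RMS error relative to the pure baseline.

The Lyapunov-decrease property is checked in the one scenario where it
is exact (`lyapunov_diagnostic()`): plant identical to the design model,
no noise, and a constant disturbance $f$ entering through $(B, D)$
exactly as the control does, so the ideal coefficients are
$\Theta = (-f, 0, \dots)$ via the constant regressor term. On a
mismatched plant the disturbance is not matched and only the empirical
tracking statements above are claimed.

## Integration and determinism

Everything is integrated with fixed-step classical RK4. The step is
$\min(\tau_{plant}/100,\; T_{cmd}/200,\; 0.5/|\lambda|_{max}(A_{ref}))$:
the third term is the explicit-integrator stability bound, which matters
because the LQR makes the reference model much faster than either the
plant or the command. Measurement noise is sampled once per step and
held through the RK4 stages; all randomness flows through the single
seed argument, so traces are bit-identical across repeat runs. The
open-loop plant simulator refuses steps above $\tau/5$ and warns above
$\tau/20$.

## Force sensing and vision

The sensing tube is an Euler–Bernoulli cantilever: a force $F$ applied at
the glue position $x_a$ deflects the tip by
$u_{tip} = F x_a^2 (3L - x_a) / (6 E_t I_z)$, summarised by a stiffness
$K = F/u_{tip}$. Calibration against a reference balance measures the
local stiffness $F/u_a$ at several positions, refers each to the tip via
the geometric factor $2x_a/(3L - x_a)$, and fits the one-parameter family
$K(x_a) = 6a/(3L x_a^2 - x_a^3)$, where $a$ plays the role of the bending
rigidity $E_t I_z$. Magnitudes are stored throughout; the deflection
direction is a flag. The default tube in the simulator (70 mm glass tube,
glued at 60 mm, $E_t I_z = 7\times10^{-2}$ N m²) has
$K \approx 0.78$ µN/µm, which puts tip deflections for µN-scale forces in
the ~10 µm range the optics can resolve.

The synthetic camera renders a dark horizontal tube on a bright
background with Gaussian pixel noise; it is a fixture generator, not an
optics model — no blur, illumination gradients, or refraction by the
bath. Detection is Otsu binarisation (no threshold is hand-set), one 3×3
dilation to suppress speckle, and a Harris corner response
($k = 0.04$, 3×3 window) restricted to the tube component; the rightmost
corner is taken as the tip because the free end of a horizontal
cantilever is its rightmost feature, with ties broken by response
strength, and the tip row is refined to the component centre. The
round-trip error is at most 2 px at the noise levels exercised, which at
the default optics (1600 px over 7.04 mm, objective factor $4\times0.5$,
i.e. 2.2 µm/px) corresponds to 4.4 µm of tip position. Pixel jitter with
the package's default $\sigma = 2.619$ px converts to
$\sigma_{um} = \sigma_{px} \times \text{µm/px}$ — the conversion is exactly
linear, and no further scaling is applied.

## Modulus extraction

Stress is $\sigma = F/S$ (kPa), strain is
$\varepsilon = (L_m - u_{tip})/L_0$ — the manipulator travel minus the
sensing-tube deflection, which in the simulator equals the fiber
elongation identically. The `drop_u_tip` flag provides the common
approximation $\varepsilon \approx L_m/L_0$; with the default compliant
tube the deflection share is large and the approximation is poor, so the
full expression is the default. The default fiber is 150 µm in diameter
($S = \pi d^2/4$) with a 1 mm gauge length.

Both signals are fitted with phase-shifted sinusoids — linear least
squares on a sin/cos basis at the known drive frequency, or
periodogram-seeded Levenberg–Marquardt when the frequency is free — after
discarding the first cycle of transient. The cyclic modulus is
$E_c = \sigma_0/\varepsilon_0$. The elliptical Lissajous loop yields the
same number geometrically: the principal axis of the
amplitude-normalised ellipse meets the curve at
$(\varepsilon_0, \sigma_0)\cos(\Delta/2)$, so the projection ratio
$L_y/L_x$ equals $\sigma_0/\varepsilon_0$ exactly; the package computes
the projections by principal-component analysis of the sampled loop and
asserts the equality to $10^{-6}$ as a cross-check. Dissipation per
cycle is $\pi\sigma_0\varepsilon_0|\sin\Delta|$ with
$\Delta = \delta - \varphi$ the stress–strain phase lag, verified against
the numerically integrated contour area.

Against the analytic SLS dynamic modulus $|G(i\omega)| L_0/S$, the
measured $E_c$ is reproduced within 2 %; the residual is dominated by
transient truncation, which is why one full cycle is discarded before
fitting. $E_c$ is insensitive to the command amplitude (linearity) and
nearly insensitive to frequency in the exercised band, with a
coefficient of variation below 5 % across amplitudes $\{3,4,5,6\}$ µN
and frequencies $\{0.005, 0.01, 0.02\}$ Hz.

One subtlety about dissipation versus frequency: for an SLS element the
loss modulus peaks at $\omega\tau = 1$, i.e. at the corner frequency
$1/(2\pi\tau) \approx 0.0035$ Hz for the 7 % preset. Loop area grows
with frequency *below* the corner and shrinks above it. The package's
ordering check (`loop_area_vs_frequency()`) therefore documents the
monotone-increase expectation as valid below the corner, and the tests
exercise it at 0.5–2 mHz; in the 5–20 mHz band the same model predicts
the opposite ordering, a model property worth knowing before comparing
against bench observations at those frequencies.

The constant-force ramp alternative (`simulate_ramp_loading()`,
10 mm/min, 0.2 s sampling) fits a line to stress–strain over the loading
phase. Because the fiber relaxes underway, the slope falls as the window
grows: the first-2-sample and first-3-sample fits are steeper than the
full-record fit, which is the mechanism by which ramp fitting
under-reports the modulus of soft fibers. On short ramps the two methods
agree: $E_{cf}$ is within 5 % of $E_c$ on the same plant.

## Relaxation fitting and its statistical limits

`fit_sls()` fits the relaxation curve by Levenberg–Marquardt with
moment-based starting values, reports $R^2$ and convergence, and flags
the degenerate case $\lambda_2 \approx 0$ (a constant record), where
$\tau$ is unidentifiable, instead of returning fabricated values.

On noiseless synthetic curves the fit recovers all three parameters to
well under 0.1 % from a start displaced by +50 %. Under additive noise
the parameters are *not* equally estimable: $\lambda_1$ is pinned by the
long plateau, but all information about $\tau$ lives in the decaying
branch of amplitude $\lambda_2 u_0$. The Fisher information of $\tau$
for this model gives a relative standard deviation of several percent
when the noise standard deviation is 1 % of the initial force
(for the 7 % preset sampled at 0.5 s over 200 s the bound is ≈ 7.8 %),
so percent-level recovery of $\tau$ at that noise level is impossible
for any estimator — a sampling-design fact, not a fitter deficiency. The
test suite asserts the achievable statements: sub-2 % $\lambda_1$
recovery, an $R^2$ concentrating at its signal-to-noise ceiling
$\mathrm{var}(F)/(\mathrm{var}(F) + \sigma^2)$, and $\tau$ errors
consistent with the information bound.

## Problem sizes

The reference study uses 3 loading cycles at 0.01 Hz per closed-loop run
(≈ 23 000 RK4 steps), 100-seed replicates for the Monte-Carlo statements,
50 rendered frames for the detection round trip, and a 20-cycle run for
the boundedness check. These sizes keep every statement statistically
meaningful while the whole suite remains desk-scale.

## Known limitations

* The plant is linear viscoelastic by construction: no large-strain
  stiffening, no Poisson thinning, no multi-branch relaxation spectra.
  Passing tests certify the pipeline against this model class, not
  against real GelMA fibers.
* The adaptive law's decrease certificate applies to matched
  disturbances; robustness to realisation mismatch is demonstrated
  empirically (two presets, one controller), not proven.
* The camera model omits blur and illumination structure, so the 2 px
  detection bound should be read as a clean-image property.
* No actuator saturation, backlash or frame-rate limits are modelled;
  the simulator's manipulator is ideal.
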