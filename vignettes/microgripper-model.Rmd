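---
title: "Modelling a rotary comb-drive cell microgripper: actuation, dynamics, and modulus inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a rotary comb-drive cell microgripper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripsim)
```

## The device and the measurement idea

`gripsim` models a surface-micromachined MEMS microgripper built to squeeze
single biological cells, aimed at telling circulating tumour cells (CTCs)
apart from benign cells by their mechanics: malignant cells are typically
softer than benign ones. The device has a fixed arm and a mobile arm
suspended on two polysilicon serpentine springs. Two rotary comb-drive
actuators rotate the mobile arm about the spring pivot: a dc-driven comb
(120 finger pairs per layer, three mobile layers) opens and closes the tips
to catch a cell, and an ac-driven comb (20 pairs per layer) oscillates the
arm so the tips squeeze the gripped cell at the arm's rotational resonance.
The tips start 40 µm apart and the controlled travel is 40 µm in either
direction, so the maximum opening is 80 µm.

A gripped cell resists the squeezing. Its contact stiffness adds to the
suspension stiffness, raising the arm's rotational resonant frequency and
quality factor. The measurement inverts that shift: locate the loaded
resonance, subtract the known free resonance, and map the stiffness excess
back to the cell's elastic modulus. The package implements the full forward
chain (electrostatics, suspension, damping, contact, dynamics) and the
inverse estimator, plus synthetic-data generators to validate the chain
end-to-end.

## Electrostatic actuation

For a rotary comb at overlap angle $\theta$ the capacitance is linear in
$\theta$,

$$C(\theta) = \varepsilon_0\,\theta\,h
 \left[\sum_{i=1}^{n-1}\Big(\ln\tfrac{R_0+2i(W_f+g)}{R_0+2i(W_f+g)-g}\Big)^{-1}
 + \sum_{i=1}^{n-1}\Big(\ln\tfrac{R_0+(2i+1)(W_f+g)}{R_0+2i(W_f+g)+W_f}\Big)^{-1}\right]
 \times \mathrm{layers},$$

with $R_0$ the inner finger radius, $W_f$ the finger width, $g$ the gap and
$h$ the layer thickness. Because $C$ is linear in $\theta$, the torque
$\tau = \tfrac12 (\partial C/\partial\theta) V^2 = \tau_0 V^2$ is constant
over the stroke. The sums run over $n-1$ finger interfaces exactly as the
source model states them; whether they should run over $n$ is an open
modelling question we deliberately did not "correct" (the difference is one
interface in 19).

The squeezing comb is driven push-pull, $V_L = V_0 + V_1\sin\omega t$ and
$V_R = V_0 - V_1\sin\omega t$, whose net effect is a purely alternating
torque $B\sin\omega t$ with $B = 4\tau_0 V_0 V_1$. Under a peak-voltage cap
$V_0 + V_1 \le V_c$ the torque amplitude is maximised by the equal split
$V_0 = V_1 = V_c/2$ (`optimal_pushpull()`); with the device's 129.2 V cap
that is 64.6 V per component. The side-instability limit
$V_c = g\sqrt{k/2C}$ guards against lateral snap-in of the fingers; the
lateral stiffness defaults to the suspension's in-plane $k_{Fy}$, the
direction normal to the finger sidewalls, and is configurable.

## Serpentine suspension

The suspension is analysed by Castigliano's second theorem on a chain of
straight Euler–Bernoulli beams: the strain energy keeps tension, Saint-
Venant torsion, and bending in both planes, with internal loads from rigid
statics of the tip load; deflections are exact derivatives of the
resulting quadratic form (no numerical differencing). The rectangular
section uses $I = bh^3/12$ and the classical tanh-series torsion constant
(16 terms by default; at 12 terms the square-section coefficient is already
$0.1406\,h^4$ to four digits). The two mirrored springs act in parallel, so
assembly stiffnesses are twice the single-spring values; the five printed
reference stiffnesses are treated as assembly totals.

An independent space-frame finite-element oracle (12-dof Euler–Bernoulli
elements, assembled in µm–N units for conditioning) cross-checks every
stiffness; the property-based tests hold the two routes to within 2% over
randomized slender serpentines, and they agree to many more digits because
both are exact for point tip loads.

The reference design's beam artwork is not published — only the stiffness
set is. The package therefore ships the printed stiffness set as the
authoritative `direct`-mode suspension, and additionally a *calibrated*
serpentine geometry (`default_serpentine()`): a 4-leg/3-link chain of
4 µm × 7 µm section whose total length is fixed by the closed form
$k_{tz} = 2EI_z/L_{\mathrm{tot}}$ to reproduce the reference
$k_{tz} = 49{,}557$ µN µm rad⁻¹. Only $k_{tz}$ is calibrated; a one-time
search over plausible constant-section serpentines could not bring all five
stiffnesses within 0.5% simultaneously (best ≈ 20%), so the other four
follow from the invented geometry and the direct mode remains the default.

## Air damping

Operating in air (liquid immersion is out of scope), the arm loses energy
to slide films: the substrate film under the first mobile layer
($\mu A_p r^2/d_p$ per body above the substrate), the drag of the upper
mobile layers ($\tfrac{32}{3}\mu\, l\, r^2$ per body, counted twice for the
two identical upper layers), and the films in the comb sidewall gaps
($\mu A_s r^2/g$ per face). Every coefficient is a *rotational* damping
coefficient — local Couette drag weighted by the squared lever arm about
the pivot — so the total $c_{amT} = c_{am1} + 2c_{am2} + c_{am4}$
multiplies $\dot\theta_z$ directly in the equation of motion. That reading
makes the damping term dimensionally consistent; the source presentation
mixes force and torque language and prints no numeric damping value, so
there is nothing to verify against.

The arm partition (three bodies: a hub over the etched pit and two outer
sections above the substrate) and the sidewall list are shipped defaults at
plausible dimensions for this device class; they give a quality factor of
about 63 for the unloaded arm, typical for such resonators in air. All of
it is configuration data.

## Cell contact and its cubic reduction

The gripped cell is a linear-elastic sphere (radius $R$, modulus $E_c$,
Poisson ratio $v$, default 0.5 as is conventional for cells — the source
work cites measured moduli but prints no $v$). Squeezing by a radial
compression $\delta_r$ flattens a cap of chord radius
$a = \sqrt{2R\delta_r - \delta_r^2}$, and the restoring force follows a
large-deformation Hertzian law with a lateral-extension correction
$f(a)$:

$$F = \frac{\delta_r E_c}{3(1-v^2)}\Big(4a - \frac{f(a)\,a^2}{\pi}\Big),
\qquad
f(a) = \frac{2(1+v)R^2}{(a^2+4R^2)^{3/2}} + \frac{1-v^2}{(a^2+4R^2)^{1/2}}.$$

The printed source bracket is dimensionally inconsistent ($4a$ is a length,
$f(a)/\pi$ an inverse length); the package's documented normalisation
multiplies the correction by $a^2$, the natural squared contact length, so
both terms are lengths. In the small-compression limit the force then
reduces to the sphere-plate power law
$F = \tfrac{4\sqrt2}{3}\,\frac{E_c\sqrt R}{1-v^2}\,\delta_r^{3/2}$ — the
Hertz form with the $\sqrt2$ prefactor that comes from using the geometric
chord radius in place of the Hertz elastic contact radius. A regression
test freezes the 3/2 exponent and this prefactor. The contact law is
confined behind `resistive_force()`/`resistive_torque()` so an alternative
law can be swapped in at that surface.

The arm rotation $\theta_z$ splits compression equally between the two
tips, $\delta_r = r_c\theta_z/2$ with $r_c$ the contact lever arm, and the
resistive torque $T_c = F\,r_c$ is reduced for the dynamics to an odd cubic
through the origin, $T_c \approx \alpha_a\theta_z + \alpha_b\theta_z^3$, by
least squares over the squeezing range (default: up to 20% compression of
the cell radius, $\theta_z \le 0.0016$ rad at the default lever). An odd
cubic with no constant term is the physically admissible choice:
$T_c(0) = 0$. Both coefficients are exactly proportional to $E_c$, which is
what makes the inverse problem a single division.

```{r fit}
fit_cubic_torque(cell_model(E_c = 2797, v = 0.5, R = 10e-6, label = "BHP"),
                 kinematics_model())
```

## Lever arms

The published analysis never prints the arm dimensions; two lever arms are
back-derived and kept as independent knobs. The tip lever
$r_\mathrm{tip} = 250$ µm makes the maximum dc rotation of 0.382 rad
correspond to 95.5 µm of tip travel; the contact lever $r_c = 2500$ µm
follows from inverting $r_c = 2\delta_r/\theta_z$ with $\delta_r = 2$ µm at
$\theta_z = 0.0016$ rad. The two are mutually inconsistent if read as one
physical arm — we retain both, each serving the role its defining relation
gives it, and both configurable.

## Duffing dynamics by Ritz averaging

With a gripped cell the arm obeys

$$J_b\ddot\theta_z + c_{amT}\dot\theta_z + (k_{tz}+\alpha_a)\theta_z
 + \alpha_b\theta_z^3 = B\sin\omega t,$$

a hardening Duffing oscillator. The steady state is approximated by the
single-harmonic ansatz $\theta_z = c_1\sin(\omega t - \Psi)$ (the sin-lag
convention is the one consistent with the phase relation; amplitudes are
convention-independent), giving per frequency the amplitude equation

$$\big[(k-J_b\omega^2)c_1 + \tfrac34\alpha_b c_1^3\big]^2
 + (c_{amT}\,\omega\,c_1)^2 = B^2,$$

a cubic in $c_1^2$ solved exactly (`polyroot`); on triple-root intervals
the intermediate branch is the unstable one. The linear limit
($\alpha_b = 0$) collapses to the textbook resonance curve and the tests
hold the two equal to 12 digits. A time-domain integrator (`deSolve`,
adaptive `lsoda`) serves as the independent oracle: steady-state amplitudes
agree with the stable Ritz branch within 2% at the shipped drive levels,
ringdown decay rates match $c_{amT}/2J_b$ within 1%, and drive work
balances dissipation per steady cycle within 0.5%.

The quality factor uses the half-power bandwidth on the upper stable
branch; for hardening-bent peaks whose branch ends at a fold before
recrossing the half-power level, the fold frequency closes the band. This
operational definition is frozen in a regression test because the source
defines $Q$ only verbally.

The unloaded arm resonates at

```{r freq}
resonant_frequency(49557e-12, 5.86e-15)
```

Hz — with the published stiffness and inertia this lumped formula gives
462.8 Hz, 0.2% below the 463.8 Hz the reference analysis reports for the
same inputs (its FEM counterpart is 463 Hz).

## Modulus inference

`estimate_modulus()` is the package's fitted-model interface: it takes a
measured `(frequency, amplitude)` table and a scenario, and returns a
`modulus_fit` with `print`/`summary`/`coef`/`confint`/`predict`/`plot`
methods. Two routes are computed:

* **frequency_shift** (headline): the loaded peak is located by quadratic
  interpolation around the grid maximum (the frozen peak-extraction rule);
  $\hat k_{zc} = 4\pi^2 J_b (f_\mathrm{loaded}^2 - f_\mathrm{free}^2)$,
  minus the Duffing backbone term $\tfrac34\alpha_b c_\mathrm{peak}^2$ at
  the measured operating amplitude (the peak sits on the backbone, not at
  the linear natural frequency; a 4-round fixed-point iteration suffices
  because the correction is small). The stiffness maps to modulus by one
  division, since $\alpha_a \propto E_c$.
* **torque_balance**: the cell torque is reconstructed per sweep sample
  from the steady-state ansatz, $T_\mathrm{cell} = B\sin\omega t -
  J_b\ddot\theta - c_{amT}\dot\theta - k_{tz}\theta$, its linear
  coefficient separated by regressing the reconstructed torque on
  $(c_1, \tfrac34 c_1^3)$, and the same contact-geometry map inverted. We
  regress rather than divide per sample because harmonic balance folds the
  cubic coefficient into the response with a 3/4 weight: a pointwise
  division by the contact factor is systematically biased (tens of percent
  at operating amplitudes well below the fit range), while the regression
  removes exactly that redistribution. This route is validated by
  round-trip self-consistency only.

Uncertainty comes from a parametric bootstrap: the relative noise level is
estimated from first differences of the measured curve, fresh
multiplicative noise at that level is layered on, and the estimate is
recomputed (50 draws by default; 95% percentile interval). Re-noising the
measurement rather than a smooth of it avoids biasing the peak downward
and makes the interval mildly conservative — coverage in the tests runs
above the nominal level. Classification assigns the label with the
smallest absolute z-score against the reference table (BHP 2797 ± 491 Pa,
PC-3 1401 ± 162 Pa, LNCaP 287 ± 52 Pa, all 10 µm radius); exact ties break
towards the stiffer class with a warning.

```{r infer}
scn <- scenario_preset("cell_BHP")
meas <- make_synthetic_measurement(scn, noise_sd = 0.01, seed = 7)
fit <- estimate_modulus(meas, scn, bootstrap = 50, seed = 7)
summary(fit)
```

## What the synthetic data does and does not emulate

`make_cell_population()` draws moduli from the reference mean ± sd
(truncated normal, redrawing non-positive values — the simplest
distribution consistent with a printed mean ± sd summary) at fixed radius.
`make_synthetic_measurement()` returns the Ritz upper stable branch with
multiplicative Gaussian amplitude noise. This emulates an ideal capacitive
read-out with amplitude-proportional noise. It does *not* emulate:
frequency jitter or drift, read-out circuit dynamics, sweep hysteresis
through the fold region, cell viscoelasticity or adhesion, misalignment of
the cell between the tips, or liquid-environment damping. Green round-trip
tests therefore certify the inference chain against the package's own
forward model under those idealisations — not against real measurements.

## Numerical choices and problem sizes

* Internal units are SI throughout; configuration files use tagged
  micro-scale units converted exactly once at load and save
  (round-trip-stable to 12 digits). The frame oracle assembles in µm–N
  units internally because the SI stiffness matrix of µm-scale beams is
  numerically singular.
* Default frequency grids are 1201 points over the band containing both
  free and loaded peaks (0.5 Hz spacing); tests that sweep many scenarios
  use 601–801 points over narrower bands. The Monte-Carlo checks use 40
  noise seeds (noise model), 25 trials × 3 levels (bias), and 200 trials ×
  50 bootstrap draws (coverage) — sizes at which the binomial error of the
  asserted proportions is comfortably below the asserted margins.
* The time-domain oracle integrates 220–240 forcing periods so the
  transient (decay time $2Q/\omega$) is damped below the 2% comparison
  tolerance; energy integrals use full-cycle trapezoids.
* Drive defaults ($V_0 = V_1 = 0.25$ V on the squeezing comb) keep the
  steady amplitude near $3\times10^{-4}$ rad: inside the cubic-fit range,
  small enough that the hardening peak shift is a sub-percent correction,
  large enough to dominate read-out noise.
* Degenerate inputs: a measurement whose maximum sits at the grid edge is
  refused (widen the grid); an estimated modulus outside (1, 10⁵) Pa is
  flagged, not raised; a loaded frequency below the free one is an
  inconsistency error in the stiffness inversion, and is treated as a
  flagged near-zero estimate inside the full estimator.

## Known limitations

Only the rotational-z working mode is modelled — other structural modes
need a full FEM treatment and are out of scope, as are electrostatic
fringing fields, squeeze-film and rarefied-gas damping corrections,
stress recovery in the springs, and any cell model beyond the isotropic
elastic sphere. The dc voltage limits and maximum gripping force of the
physical design depend on actuator geometry that is not published, so the
package computes them from its configurable defaults rather than
reproducing specific printed values.
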