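# gripsim

Lumped-parameter simulation of a rotary electrostatic comb-drive MEMS
microgripper that squeezes single biological cells, and inference of a
gripped cell's elastic modulus from the resonance shift it causes.

Circulating tumour cells are mechanically softer than many benign cells, so
a gripper that can measure a cell's stiffness can help tell them apart.
The device modelled here holds a cell between two tips, closes them with a
dc comb-drive, and squeezes the cell at the mobile arm's rotational
resonance with an ac push-pull comb-drive. A gripped cell of elastic
modulus $E_c$ adds rotational stiffness, shifting the resonance from

$$f_{r} = \frac{1}{2\pi}\sqrt{\frac{k_{tz}}{J_b}}
\quad\text{to}\quad
f_{r} = \frac{1}{2\pi}\sqrt{\frac{k_{tz}+\alpha_a(E_c)}{J_b}},$$

where $k_{tz}$ is the serpentine-suspension stiffness, $J_b$ the arm's
polar inertia, and $\alpha_a \propto E_c$ the linear coefficient of the
cell's resistive torque $T_c \approx \alpha_a\theta_z + \alpha_b\theta_z^3$
(a least-squares cubic reduction of a large-deformation Hertzian contact
law). The forced dynamics are a hardening Duffing oscillator,

$$J_b\ddot\theta_z + c_{amT}\dot\theta_z + (k_{tz}+\alpha_a)\theta_z
 + \alpha_b\theta_z^3 = B\sin\omega t,\qquad B = 4\tau_0 V_0 V_1,$$

solved in steady state by Ritz averaging (harmonic balance). The package
covers the whole chain:

* **electrostatics** — rotary comb capacitance, torque coefficient
  $\tau_0$, push-pull drive, side-instability voltage limit, static
  rotation and gripping-force reserve;
* **springs** — Castigliano energy-method stiffness of the serpentine
  suspension, rectangular-section properties (tanh-series torsion
  constant), plus a space-frame finite-element oracle;
* **damping** — slide-film air damping of the arm bodies, upper layers and
  comb sidewalls, combined into one rotational coefficient;
* **cell contact** — Hertzian large-deformation force/torque of the
  gripped cell and its cubic reduction;
* **dynamics** — Ritz frequency response with branch/stability
  bookkeeping, resonant frequency, quality factor, time-domain integration
  oracle;
* **inference** — `estimate_modulus()`, a fitted-model interface returning
  a `modulus_fit` object (print/summary/coef/confint/predict/plot), with
  frequency-shift and torque-balance estimates, bootstrap intervals, and
  classification against reference prostate cell lines (BHP, PC-3, LNCaP);
* **fixtures** — scenario presets, YAML configuration with explicit units,
  synthetic cell populations and noisy synthetic measurements.

## Worked example

Simulate a benign prostate (BHP) cell gripped by the default device,
generate a noisy synthetic read-out of the frequency response, and invert
it:

```r
library(gripsim)

scn  <- scenario_preset("cell_BHP")                        # E_c = 2797 Pa
meas <- make_synthetic_measurement(scn, noise_sd = 0.01, seed = 42)
fit  <- estimate_modulus(meas, scn, bootstrap = 50, seed = 42)
summary(fit)
```

```
Cell modulus estimate from microgripper resonance

Free resonance   :   462.83 Hz
Loaded peak      :   676.07 Hz  (amplitude 0.000186 rad)

Estimates by method:
  frequency_shift  E_hat =   2800.1 Pa   k_zc = 5.58e-08 N m/rad
  torque_balance   E_hat =   2796.1 Pa   k_zc = 5.572e-08 N m/rad

95% bootstrap CI : 2794.1 - 2804.1 Pa (50 draws)

Classification z-scores:
  BHP       0.01
  PC-3      8.64
  LNCaP    48.33
Assigned class: BHP
```

Reading this: the unloaded arm resonates at 462.8 Hz (from the reference
stiffness 49,557 µN µm rad⁻¹ and inertia 5.86×10⁻³ kg µm²); gripping the
cell raises the peak to 676 Hz; inverting the shift recovers the cell's
rotational stiffness (≈5.6×10⁻⁸ N m rad⁻¹) and, through the contact law,
its modulus — within ~0.1% of the simulated truth here — and the z-scores
assign it unambiguously to the benign class. `plot(fit)` overlays the
model response at the estimate on the measurement.

A shell interface wraps the same functions
(`exec/gripsim`, installed with the package):

```sh
gripsim sweep  --config cell_BHP --fmin 300 --fmax 900 --points 1201 --out resp.csv
gripsim infer  --config cell_BHP --measurement resp.csv --out estimate.json
gripsim stiffness --config paper_default
```

Every file-writing subcommand drops a `*.manifest.json` (config hash, seed,
version, timestamp, command line) next to its output.

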