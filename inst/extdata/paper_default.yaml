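# Default microgripper scenario: published electrode dimensions, suspension
# stiffness set, inertia; shipped defaults for the unpublished arm artwork
# (damping partition, lever arms, drive level).  Every dimensioned field is
# a {value, unit} pair; bare numbers use the documented default unit.
comb_electrostatic:          # dc open/close actuator, 120 pairs per layer
  R0: {value: 400, unit: um}
  Wf: {value: 2, unit: um}
  g: {value: 2, unit: um}
  h: {value: 7, unit: um}
  "n": 120
  layers: 3
  theta0: {value: 6, unit: deg}
comb_electrodynamic:         # ac squeezing/sensing actuator, 20 pairs per layer
  R0: {value: 400, unit: um}
  Wf: {value: 2, unit: um}
  g: {value: 2, unit: um}
  h: {value: 7, unit: um}
  "n": 20
  layers: 3
  theta0: {value: 6, unit: deg}
suspension:
  mode: direct
  E: {value: 160, unit: GPa}
  nu_poly: 0.23
  rho: {value: 2330, unit: kg_m3}
  stiffness:                 # two-spring assembly totals
    k_tz: {value: 49557, unit: uN_um_per_rad}
    k_tx: {value: 11982, unit: uN_um_per_rad}
    k_Fx: {value: 25.74, unit: uN_per_um}
    k_Fy: {value: 90.76, unit: uN_per_um}
    k_Fz: {value: 10.14, unit: uN_per_um}
inertia:
  J_b: {value: 5.86e-3, unit: kg_um2}
damping:
  d_p: {value: 2, unit: um}
  g: {value: 2, unit: um}
  mu: {value: 1.81e-5, unit: Pa_s}
  bodies:
    - {A_p: {value: 30000, unit: um2}, r_am: {value: 150, unit: um},
       l_am: {value: 150, unit: um}, above_substrate: false}
    - {A_p: {value: 20000, unit: um2}, r_am: {value: 400, unit: um},
       l_am: {value: 100, unit: um}, above_substrate: true}
    - {A_p: {value: 15000, unit: um2}, r_am: {value: 575, unit: um},
       l_am: {value: 75, unit: um}, above_substrate: true}
  sidewalls: auto            # generated from the electrodynamic comb
kinematics:
  r_tip: {value: 250, unit: um}
  gap0: {value: 40, unit: um}
  r_c: {value: 2500, unit: um}
  max_travel: {value: 40, unit: um}
drive:
  V0: 0.25
  V1: 0.25
  omega: 0
  Vdc: 23.4
solver:
  freq_min: 300
  freq_max: 900
  freq_points: 1201
  branch_policy: stable
  ode_rtol: 1.0e-8
  ode_atol: 1.0e-12
  seed: 1
  series_terms: 16
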