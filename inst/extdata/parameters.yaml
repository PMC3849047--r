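# Default parameter set for the mouse alveolar nanoparticle toxicodynamic model.
# Units are recorded as strings next to each block. Rate constants are in 1/min
# unless stated otherwise; amounts are umol per g lung; concentrations umol/ml.

body_weight_g: 24.82

phospholipid_composition:
  units: {molecular_weight: g/mol, percent: "%"}
  species:
    - {name: PC, molecular_weight: 760.076, percent: 78}
    - {name: PE, molecular_weight: 471.609, percent: 3}
    - {name: PS, molecular_weight: 547.17,  percent: 5}
    - {name: PG, molecular_weight: 787.383, percent: 7}
    - {name: SM, molecular_weight: 646.505, percent: 2}
    - {name: CL, molecular_weight: 400.637, percent: 5}

protein_molecular_weights:
  units: g/mol
  SP_A: 26000
  SP_B: 8700
  SP_C: 3700
  SP_D: 39000

morphology:
  units:
    total_lung_volume_ml: ml
    total_lung_mass_g: g
    alveolar_fluid_ml_per_kg_bw: ml/kg
    alveolar_surface_m2: m^2
    interface_thickness_um: um
    at2_cell_volume_um3: um^3
    at2_count_per_g_lung: 1/g
    macrophage_count: count
    lb_volume_per_at2_um3: um^3
    lb_count_per_at2: count
  total_lung_volume_ml: 1.43
  total_lung_mass_g: 0.43
  alveolar_fluid_ml_per_kg_bw: 10
  alveolar_surface_m2: 0.0082
  interface_thickness_um: 0.2
  at2_cell_volume_um3: 385.7
  at2_count_per_g_lung: 9.13e+7
  macrophage_count: 1.66e+5
  lb_volume_per_at2_um3: 61.3
  lb_count_per_at2: 150

# Regulatory constants: linear-in-concentration factors on delivery processes.
# Constants are per umol/ml of the regulator. `concentration_scale` sets the
# scale on which regulator concentrations enter the factors in the default
# calibration: on the mol/ml scale the corrections are small perturbations at
# physiological concentrations, which is the only reading under which the
# optimized rate table admits a non-negative steady-state calibration.
regulation:
  units: per umol/ml
  concentration_scale: mol_per_ml   # or umol_per_ml
  k_adsorption_SA: 7.312e+4
  k_adsorption_C: 2.185e+5
  k_secretion_inhibition_C: 1.7342e+3
  k_recycle_activation_C: 3.078e+4

# Optimized per-species rate constants (1/min). Direct secretion exists only
# for collectins. Degradation entries of ~calibrate~ are replaced at model
# build time by the steady-state closure of the alveolar-fluid balance.
rates:
  units: 1/min
  K_Sec:  {PL: 3.833e-5, SA: 3.833e-5, C: 3.833e-5}
  K_CSec: {PL: 0.0, SA: 0.0, C: 8.456e-5}
  K_LB:   {PL: 0.002, SA: 0.002, C: 0.002}
  K_Re:   {PL: 1.798e-5, SA: 1.798e-5, C: 9.63e-4}
  K_Ad:   {PL: 3.795e-5, SA: 0.0402, C: 0.0402}
  K_Des:  {PL: 0.0053, SA: 0.0053, C: 0.0053}
  K_Deg:  {PL: calibrate, SA: calibrate, C: calibrate}
  K_AW:   {PL: 2.083e-5, SA: 2.083e-5, C: 2.083e-5}

# Literature initial estimates (bracketed values), used as starting points for
# constrained refinement and for the steady-state estimation of the
# non-identifiable constants.
rates_literature:
  units: 1/min
  K_Sec: 3.833e-5
  K_LB: 0.0035
  K_Re: 0.0025
  K_Ad: 0.0402
  K_AW: 2.083e-5

# Reference (steady-state) amounts, umol per g lung.
reference_state:
  units: umol/g lung
  AT2: {PL: 10.0,   SA: 0.175,      C: 1.7848}
  LB:  {PL: 1.14,   SA: 1.995e-2,   C: 6.8e-6}
  AF:  {PL: 0.0818, SA: 0.0035,     C: 0.0146}
  Int: {PL: 1.46,   SA: 0.0301,     C: 0.0151}

# Equilibrium interface amounts: closed from the interface balance where
# feasible; otherwise this multiple of the reference interface amount.
film:
  m_eq_fallback_ratio: 2.0

surfactant_density:
  units: mg/ml
  value: 1040

coating_thickness_nm: 4

# Michaelis-Menten binding of interfacial PL to particle surface area.
binding:
  units: {V_A: mg/s/ml, K_A: m^2/ml}
  oxidized:     {V_A: 5.1e-3,   K_A: 1.03e-2}
  non_oxidized: {V_A: 3.581e-3, K_A: 1.131e-2}

# Particle transport at the interface: coated particles are flushed into the
# alveolar fluid quickly (first-order stand-in for per-breath exchange);
# a fraction of naked particles transfers per minute. f_naked is a provisional
# default, not a literature value.
np_transport:
  units: 1/min
  k_coated_transfer: 10
  f_naked: 0.01

elimination:
  units: 1/min
  K_El: 3.511e-4   # exponent provisional; see documentation

deposition:
  units: fraction
  intratracheal_pulmonary_fraction: 0.5218
  inhalation_alveolar_fraction_15nm: 0.4026

# Alveolar cell physical properties and uptake kinetics. phi is tissue
# porosity; gamma an intrinsic cell-type affinity (dimensionless, absorbs the
# adhesion-model scale constant). V_max in particles/min/cell, K_m in
# particles/ml. V_max/K_m and gamma are literature-guided defaults; the AT1
# census is not in the morphology table and is a configurable estimate.
cells:
  AT1:
    phi: 0.04
    diameter_um: 75
    gamma: 1.0
    count: 3.3e+7
    V_max: 1.0
    K_m: 1.0e+9
    F_size_knots:  {x: [10, 100, 1000], f: [1.0, 0.6, 0.1]}
    F_zeta_knots:  {x: [-60, 0, 60],    f: [0.2, 0.5, 1.0]}
  AT2:
    phi: 0.97
    diameter_um: 10
    gamma: 1.0
    count: from_morphology   # at2_count_per_g_lung x total_lung_mass_g
    V_max: 1.0
    K_m: 1.0e+9
    F_size_knots:  {x: [10, 100, 1000], f: [1.0, 0.6, 0.1]}
    F_zeta_knots:  {x: [-60, 0, 60],    f: [0.2, 0.5, 1.0]}
  Mph:
    phi: 0.99
    diameter_um: 11.2
    gamma: 500.0
    count: from_morphology   # macrophage_count
    V_max: 10.0
    K_m: 5.0e+8
    F_size_knots:  {x: [10, 100, 1000], f: [0.3, 0.6, 1.0]}
    F_zeta_knots:  {x: [-60, 0, 60],    f: [1.0, 0.2, 0.1]}

# Default particle specifications.
particles:
  nAg:
    material: silver
    diameter_nm: 15
    density_g_cm3: 10.49
    zeta_mV: -9.6
    zeta_coated_mV: -39.2
    oxidized: true
  CB:
    material: carbon black
    diameter_nm: 15
    density_g_cm3: 1.9
    zeta_mV: -9.6
    zeta_coated_mV: -39.2
    oxidized: false

# Surfactant coupling of the Constant Phase Model parameters:
# X* = X (1 + k_X * dCs), dCs the relative interfacial PL deficit vs control.
cpm_coupling:
  units: dimensionless
  k_R: 0.1
  k_G: 0.5
  k_H: 0.5

solver:
  rtol: 1.0e-8
  atol: 1.0e-12
  output_step_min: 1

# Sensitivity census: 10 physiological + 30 biochemical + 6 particle-specific.
sensitivity_census:
  physiological:
    - morphology.total_lung_volume_ml
    - morphology.total_lung_mass_g
    - morphology.alveolar_fluid_ml_per_kg_bw
    - morphology.alveolar_surface_m2
    - morphology.interface_thickness_um
    - morphology.at2_cell_volume_um3
    - morphology.at2_count_per_g_lung
    - morphology.macrophage_count
    - morphology.lb_volume_per_at2_um3
    - morphology.lb_count_per_at2
  biochemical:
    - rates.K_Sec.PL
    - rates.K_Sec.SA
    - rates.K_Sec.C
    - rates.K_CSec.C
    - rates.K_LB.PL
    - rates.K_LB.SA
    - rates.K_LB.C
    - rates.K_Re.PL
    - rates.K_Re.SA
    - rates.K_Re.C
    - rates.K_Ad.PL
    - rates.K_Ad.SA
    - rates.K_Ad.C
    - rates.K_Des.PL
    - rates.K_Des.SA
    - rates.K_Des.C
    - rates.K_Deg.PL
    - rates.K_Deg.SA
    - rates.K_Deg.C
    - rates.K_AW.PL
    - rates.K_AW.SA
    - rates.K_AW.C
    - regulation.k_adsorption_SA
    - regulation.k_adsorption_C
    - regulation.k_secretion_inhibition_C
    - regulation.k_recycle_activation_C
    - M_eq.PL
    - M_eq.SA
    - M_eq.C
    - elimination.K_El
  particle_specific:
    - particle.diameter_nm
    - particle.density_g_cm3
    - particle.zeta_mV
    - particle.V_A
    - particle.K_A
    - np_transport.f_naked
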