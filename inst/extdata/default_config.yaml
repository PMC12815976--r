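# Default run configuration: 1000-subject virtual population, four IV
# atezolizumab regimens, two-compartment model with covariates and IIV.
#
# Structural parameters, covariate effects and IIV magnitudes under `model`
# are EXTERNALLY SOURCED: transcribed from the published atezolizumab
# population-PK model (Stroh et al., CPT Pharmacometrics Syst Pharmacol 2017;
# FDA CDER clinical pharmacology review for atezolizumab). Units: CL and Q in
# L/day, V1 and V2 in L, time in days, doses in mg, concentrations in ug/mL.

seed: 20260101

population:
  n_subjects: 1000
  age_min: 20          # years
  age_max: 80
  p_male: 0.5
  weight_intercept_f: 65   # kg at age 40
  weight_intercept_m: 85
  weight_age_slope: 0.75   # kg/year
  weight_sd_f: 3.5         # kg (Gaussian noise SD)
  weight_sd_m: 10
  albumin_log_median: 42   # g/L, natural-scale median
  albumin_log_sd: 0.10     # ln-scale SD (calibrated to reference min-max range)
  tumor_log_location: 4.2  # ln(mm); median exp(4.2) ~ 66.7 mm
  tumor_log_sd: 0.70       # ln-scale SD (calibrated to reference min-max range)
  p_ada: 0.40

model:
  structural:          # typical values [externally sourced, see header]
    cl: 0.200          # L/day
    v1: 3.28           # L
    q: 0.546           # L/day
    v2: 3.63           # L
  covariate_effects:   # power: param * (x/reference)^value; proportional: * (1+value)
    - {parameter: cl, covariate: weight,     kind: power,        reference: 77, value: 0.808}
    - {parameter: cl, covariate: albumin,    kind: power,        reference: 40, value: -1.12}
    - {parameter: cl, covariate: tumor_size, kind: power,        reference: 63, value: 0.125}
    - {parameter: cl, covariate: ada,        kind: proportional, value: 0.159}
    - {parameter: v1, covariate: weight,     kind: power,        reference: 77, value: 0.559}
    - {parameter: v1, covariate: sex,        kind: proportional, value: -0.129, level: female}
  omega_sq:            # ln-scale variances (IIV)
    cl: 0.0841         # ~29% CV
    v1: 0.0324         # ~18% CV

regimens:              # built-in names; custom blocks may be given instead
  - "1200 mg q3w"
  - "840 mg q2w x2, 840 mg q6w x5"
  - "1200 mg q3w x2, 840 mg q6w x5"
  - "1680 mg q4w x2, 840 mg q6w x5"

grid:
  resolution: 0.1      # days between observations within a cycle

infusion_duration_days: 0.0416666667   # 1 hour

mec: 6                 # ug/mL minimum effective concentration reference line
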