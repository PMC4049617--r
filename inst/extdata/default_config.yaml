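# Default (HeLa-like) glycolysis model configuration.
#
# Provenance of constants:
#  - Isozyme-discriminating constants (PFK F16BP activation constants,
#    PK ATP inhibition / F16BP activation / PEP half-saturation constants,
#    PFKFB tissue K/P presets) are literature values; see table1_catalog().
#  - All other kinetic constants under allosteric_constants are package
#    calibrations: scale constants chosen so that the two-enzyme F6P node
#    reproduces its switch-up/switch-down concentrations (0.3 / 0.09 mM)
#    and the full pathway reproduces the loop-dependent steady-state
#    structure; see the methods vignette.
#  - environment: fixed concentrations (mM), physiologically plausible
#    package choices.
#  - enzyme_levels: relative activities, reference state = 1.
isozymes:
  pfk:
    PFKL: 1.0
  pk: PKM2
  pfkfb:
    kp: 8.0
    level: 1.0
enzyme_levels:
  GLUT: 1.0
  HK: 1.0
  PGI: 1.0
  PFK: 1.0
  PFKFB: 1.0
  ALDO: 1.0
  TPI: 1.0
  GAPDH: 1.0
  PGK: 1.0
  PGAM: 1.0
  ENO: 1.0
  PK: 1.0
  LDH: 1.0
  MITO: 1.0
  ALA: 1.0
environment:
  ATP: 3.0
  ADP: 0.8
  AMP: 0.2
  NAD: 1.0
  NADH: 0.1
  MG: 0.5
  K: 140.0
  CA: 0.0001
  PYR_m: 0.1
  LAC: 1.5
  ALA: 0.5
  GLC_ext: 5.0
allosteric_constants:
  glut:
    Vmax: 110.0
    Km: 10.0
  hk:
    Vmax: 400.0
    Km_glc: 4.0
    Km_atp: 0.3
    Ki_g6p: 0.15
    h_g6p: 2.5
  pgi:
    Vmax: 800.0
    Km_g6p: 0.5
    Km_f6p: 0.15
    Keq: 0.3
  pfk:
    Vmax: 190.0
    Km_f6p: 0.36
    h_f6p: 1.0
    Km_atp: 0.15
    Ki_atp: 2.5
    h_iatp: 2.0
    eps: 0.016
    n_fbp: 4.0
    Ka_f26bp: 0.011
    n_f26: 4.0
    Ka_amp: 2.0
  pfkfb:
    Vph: 120.0
    kin_unit: 0.0005
    Km_f6p: 0.1
    Km_atp: 0.15
    Km_f26bp: 5.0
    Ki_pep: 0.01
    h_ipep: 2.0
  aldo:
    Vmax: 40.0
    Km_fbp: 1.0
    Km_dhap: 0.035
    Km_gap: 1.0
    Keq: 0.1
  tpi:
    Vmax: 1000.0
    Km_dhap: 0.6
    Km_gap: 0.4
    Keq: 0.5
  gapdh:
    Vmax: 92.0
    Km_gap: 0.2
    Km_nad: 0.05
    Keq: 0.08
  pgk:
    Vmax: 2000.0
    Km_bpg: 0.05
    Km_adp: 0.2
    Keq: 1800.0
  pgam:
    Vmax: 1500.0
    Km_3pg: 0.2
    Keq: 0.15
  eno:
    Vmax: 1200.0
    Km_2pg: 0.1
    Keq: 5.0
  pk:
    Vmax: 300.0
    h_pep: 2.0
    Km_adp: 0.3
    Ki_pyr: 1.0
  ldh:
    Vmax: 600.0
    Km_pyr: 0.3
    Km_nadh: 0.05
    Keq: 16000.0
  mito:
    Vmax: 20.0
    Km: 0.15
  ala:
    Vmax: 10.0
    Km_pyr: 0.5
    Keq: 5.0
cell_volume_pl: 3.0
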