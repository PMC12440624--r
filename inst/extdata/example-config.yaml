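# Example run configuration for the hetassoc CLI and read_run_config().
# Any omitted field falls back to the package default.

constants:
  C: 0.3        # fractional surface coverage [-]
  S: 4.5e-10    # cell surface area [m^2]
  V: 1.0e-10    # media volume per cell [m^3]
  u0: 1.0e+13   # initial particle concentration [particles cell^-1 m^-3]

prior:
  m_r: [1.0e-9, 1.0e-4]   # mean association rate [m s^-1]
  s_r: [1.0e-9, 1.0e-4]   # SD of association rate [m s^-1]
  m_K: [1, 500]           # mean carrying capacity [particles cell^-1]
  s_K: [0.1, 500]         # SD of carrying capacity [particles cell^-1]

abc:
  n_particles: 1000
  distance: ad            # ad | cvm | ks
  max_generations: 20

design:
  candidates: [0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24]
  k: 6
  n_pre: 2000             # production runs use far larger reference tables
  j_reps: 5
  cv: 0.1
  n_accept: 200
  n_cells: 1000

fixtures:
  cells_n: 11605
  particles_n: 500000

seed: 1
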