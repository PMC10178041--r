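# Reference thin-layer drying run: every key spelled out explicitly
# (identical to the packaged defaults).  SI units unless noted.
air:
  Ta: 42        # drying-air temperature, degC
  va: 0.75      # air velocity, m/s
  RH: 0.08      # relative humidity, fraction
geometry:
  a_kernel: 0.005   # kernel equatorial semi-axis, m
  b_kernel: 0.008   # kernel polar semi-axis, m
  t_shell: 0.001    # shell thickness, m
  mode: two_component
materials:
  shell:
    rho: 560            # dry-solid density, kg/m^3
    k_slope: 0.17062    # W/(m K) per d.b. unit
    k_intercept: 0.07753
    cp_slope: 4.04506   # kJ/(kg K) per d.b. unit
    cp_intercept: 2.05226
    D_eff: 1.63249e-10  # m^2/s
    M0: 1.24            # initial d.b. moisture, g/g
  kernel:
    rho: 1000
    k_slope: 0.32528
    k_intercept: 0.12559
    cp_slope: 1.96152
    cp_intercept: 1.15307
    D_eff: 2.91731e-10
    M0: 0.74
  pod:
    D_eff: 5.7512e-10
    M0: 0.83
bc:
  T0: 20             # initial solid temperature, degC
  M_e: 0.02          # equilibrium d.b. moisture, g/g
  f_s: 7.625079e-06  # calibrated surface-resistance factor
numerics:
  dt: 60             # time step, s
  t_end: 73800       # 1230 min
  mesh_h: 0.0005     # target element size, m
  nu_re_exp: 0.53
  sh_re_exp: 0.5
output:
  snapshot_times_s: [0, 60, 300, 1800, 3600, 7200, 14400, 36000, 72000, 73800]
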