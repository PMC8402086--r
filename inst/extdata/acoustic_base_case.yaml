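label: d0=0.5nm_Q=1
geometry_um:
  channel_length: 2000.0
  channel_height: 1000.0
  well_width: 450.0
  well_height: 380.0
  spheroid_diameter: 300.0
  well_center_x: 1000.0
  out_of_plane_depth: 1000.0
spheroid_center_um:
- 1000.0
- -190.0
fluid:
  rho0: 993.3
  mu: 0.000692
  muB: 0.0024
  Cp: 4180.0
  alpha0: 0.000275
  beta0: 4.48e-10
  ca: 1502.0
  T0: 310.15
  k_thermal: 0.62
actuation:
  f_MHz: 1.0
  d0_nm: 0.5
perfusion:
  Q_uLmin: 1.0
species:
  oxygen:
    D_medium: 2.6e-09
    D_spheroid: 1.83e-09
    S: 4.81
    Vmax: 0.0203
    Km: 0.00463
    c0_inlet: 0.2
    necrotic_threshold: 0.002644
    quiescent_threshold: 0.01322
  glucose:
    D_medium: 9.27e-10
    D_spheroid: 2.7e-10
    S: 1.0
    Vmax: 0.01076
    Km: 0.04
    c0_inlet: 5.0
    necrotic_threshold: 0.2
    quiescent_threshold: 0.5
run_options:
  streaming_mode: slip_velocity
  track_resonance: yes
  mesh:
    n_boundary_layers: 3.0
    bl_total_um: 5.0
    h_well_um: 15.0
    h_channel_um: 40.0
    growth_rate: 1.6
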