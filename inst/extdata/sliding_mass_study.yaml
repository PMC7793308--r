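model:
  inline:
    gravity:
    - 0.0
    - 0.0
    bodies:
    - name: block
      mass: 1.0
      inertia: 0.0
      parent: ground
      joint: slider
      joint_parent:
      - 0.0
      - 0.0
      joint_child:
      - 0.0
      - 0.0
      axis:
      - 1.0
      - 0.0
      com:
      - 0.0
      - 0.0
      coords: x
      coord_range:
      - -5.0
      - 5.0
      speed_range:
      - -20.0
      - 20.0
    muscles: []
    springs: []
    actuators:
    - name: force
      coord: x
      gain: 1.0
      control_range:
      - -10.0
      - 10.0
    contacts: []
    constraints: []
problem:
  t0: 0.0
  tf:
  - 0.10000000000000001
  - 5.0
  states:
  - name: x
    lower: -5.0
    upper: 5.0
    initial_lower: 0.0
    initial_upper: 0.0
    final_lower: 1.0
    final_upper: 1.0
  - name: x_u
    lower: -20.0
    upper: 20.0
    initial_lower: 0.0
    initial_upper: 0.0
    final_lower: 0.0
    final_upper: 0.0
  controls:
  - name: force
    lower: -10.0
    upper: 10.0
    initial_lower: -10.0
    initial_upper: 10.0
    final_lower: -10.0
    final_upper: 10.0
  goals:
  - kind: final_time
    weight: 1.0
    name: final_time
  parameters: []
solver:
  scheme: hermite-simpson
  n_intervals: 10
  dynamics_mode: explicit
  conv_tol: 9.99999999999999955e-07
  con_tol: 9.99999999999999955e-07
  fd_step: 9.99999999999999955e-07
  multiplier_bound: 1000.0
  gamma_bound: 0.10000000000000001
  accel_bound: 10000.0
  ftdot_scale: 50.0
  max_iterations: 3000.0
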