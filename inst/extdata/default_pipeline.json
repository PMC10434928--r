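{
  "model": {
    "mass": 72.4,
    "height": 1.8
  },
  "gait": {
    "speed": 1.25,
    "cycle_duration": 1.1
  },
  "devices": ["PF", "EV", "INV", "PF+EV", "PF+INV"],
  "peak_times": [20, 25, 30, 35, 40, 45, 50, 55, 60],
  "modes": ["muscle_driven", "torque_driven"],
  "peak_torque": 0.1,
  "integrator": {
    "accuracy": 1e-06,
    "dense_dt": 0.001
  },
  "tracking": {
    "enabled": false,
    "mesh_interval": 0.01,
    "constraint_tol": 0.0001,
    "convergence_tol": 0.01
  },
  "out_dir": "exowalk_out",
  "seed": 1,
  "log_level": "info"
}
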