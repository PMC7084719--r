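{
  "n_groups": 5,
  "workers_per_group": 20,
  "n_days": 280,
  "actual_risk": {"kind": "triangular", "low": 0.1, "mode": 0.5, "high": 0.9},
  "attitude_init": {"kind": "uniform", "low": 0.4, "high": 0.9},
  "coeff_init": {"kind": "uniform", "low": 0.6, "high": 1.2},
  "sa0": 0.8,
  "kl0": 0.8,
  "social_identity_w": 0.5,
  "norm_weights": {"coworker": 0.2, "foreman": 0.45, "manager": 0.35},
  "feedback_freqs": {"foreman_pos": 0.1, "foreman_neg": 0.6, "manager_pos": 0.1, "manager_neg": 0.6},
  "training_freq": 0.5,
  "comm_freq_coworker": 0.3,
  "comm_freq_foreman": 0.3,
  "ci_awareness": [0.01, 0.2, 0.2],
  "ci_knowledge": [0.01, 0.2, 0.1],
  "lambda_perception": 0.5,
  "a1": 0.5,
  "a2": 0.5,
  "a3": 0.5,
  "a4": 0.5,
  "c1": 0.15,
  "c2": 0.01,
  "memory_m": 0.5,
  "demo_share_d": 0.5,
  "epsilon": {"kind": "uniform", "low": -0.01, "high": 0.01},
  "env_risk_er": 0.1,
  "k_observed": null,
  "k_comm_pool": 5,
  "demo_role_enabled": true,
  "include_foremen_in_ratio": false,
  "pr_history_exclude_zeros": false,
  "coworker_memory_harmonized": false,
  "sa_cumulative": false,
  "feedback_attitude_shift": 0
}
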