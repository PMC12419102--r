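# Example simulation configuration for `vtwins simulate`.
n_hospitals: 5
sizes: [1200, 1000, 800, 600, 400]
n_covariates: 10
target_prevalence: 0.03
hospital_logit_shifts: [-0.7, -0.3, 0.0, 0.0, 0.4]
casemix_shifts: [0.0, 0.0, 0.0, 0.5, 1.5]
anomaly_fraction: 0.0
seed: 20260926
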