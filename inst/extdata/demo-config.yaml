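# Demo pipeline configuration: small synthetic problem sizes so the full
# run (synthesize -> fit -> report) completes in a few minutes on one CPU.
# Unset keys fall back to default_config().
stages:
- synth
- doseresponse
- occupancy
- pet
- eeg
out_dir: pkpd_demo_run
seed: 1
eeg:
  n_subjects: 6
  channels: 3
  duration_s: 64
  n_perm: 1000
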