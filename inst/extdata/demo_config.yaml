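# Demo pipeline configuration: a 2,000-patient synthetic cohort with
# planted known cases, suspects and near-miss decoys for both diseases.
out_dir: pipeline_out
seed: 20180101
n_patients: 2000
window:
  start: "2018-01-01"
  end: "2022-03-01"
fabry:
  n_known: 4
  n_suspect: 20
fh:
  n_known: 16
  n_suspect: 120
n_near_miss: 50
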