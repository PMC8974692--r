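# Pipeline configuration running the scoring/selection and drug-triage
# stages on the packaged study tables. out_dir is usually overridden by the
# caller (run_pipeline(modifyList(yaml::read_yaml(...), list(out_dir = ...)))).
out_dir: gwastrans_fixture_run
seed: 1
stages:
  score: true
  drugs: true
inputs:
  scorecards: fixture
  reference_genes: fixture
  drugs: fixture
overrides:
  rs61816761: FLG
params:
  score_threshold: 3
  min_score: 1.0
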