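# Fully synthetic end-to-end run: generators write a seeded input directory
# under out_dir/sim_inputs, then the proxy, scoring, PheWAS and DE stages
# run on it. Deterministic for a fixed seed.
out_dir: gwastrans_synthetic_run
seed: 1
simulate: true
sentinels:
  - snp_1
stages:
  proxy: true
  score: true
  phewas: true
  de: true
params:
  r2_min: 0.2
  n_traits: 22
  q: 0.05
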