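# Demonstration pipeline configuration: synthetic two-line dataset with
# three planted sweeps, scans, clustering, quantitative-genetic estimates
# and a small simulation design.
out_dir: divsel_demo
seed: 1
stages: [synth, scan, blockscan, clusters, quantgen, simulate]
synth:
  n_snps: 5000
  ne: 35
  sweeps:
    - {chromosome: "1", center_bp: 3.0e6, half_width_bp: 3.0e5,
       line_favoured: HIGH, fixation_generation: 30}
    - {chromosome: "2", center_bp: 2.0e6, half_width_bp: 2.0e5,
       line_favoured: LOW, fixation_generation: 45}
    - {chromosome: "3", center_bp: 1.5e6, half_width_bp: 2.0e5,
       line_favoured: HIGH, fixation_generation: 50, start_generation: 40}
quantgen:
  parents: {males: 12, females: 48}
  ne_epochs:
    n_generations: [4, 26, 15]
    ne: [27.43, 38.40, 44.80]
  otto_jones:
    - {trait: BW56, D: 670.5, M: 37.9, a_min: 34.2, n_d: 3}
simulate:
  n_rep: 200
  max_gen: 40
  hap_code: "4003"
  regimes:
    - {name: Growth12, s_male: 0.31, s_female: 0.19}
    - {name: Neutral, s_male: 0, s_female: 0}
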