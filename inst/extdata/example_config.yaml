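# Reference study configuration: four designs over the theta_B grid at
# n = 75 with 10,000 replicates per cell. Trim `replicates` (and the
# grids) for a quick smoke run.
designs:
  - design: fixed
  - design: rpw
    u: 1
    alpha: 0
    beta: 1
  - design: dp
  - design: rdp
    p: 0.9
  - design: crdp
    p: 0.9
    ell_frac: 0.15
theta_a: [0.5]
theta_b: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
n: [75]
replicates: 10000
master_seed: 20160928
alpha: 0.1
emit_trajectories: false
# output_dir: results/grid
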