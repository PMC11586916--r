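# Scenario 1 (all-exponential, group rates 0.001/0.0011/0.0004 vs
# 0.0008/0.0017/0.0009) under exponential random censoring.
# Full-size study: N = 1000, B = 250. The reduced N here is a smoke
# preset; raise N (or pass --N on the command line) for publication-grade
# Monte Carlo error.
scenario: scenario1
n_pairs:
- [200, 200]
- [300, 300]
- [500, 500]
deltas: [0.0006, 0.001, 0.0015]
censoring:
- random:0.001
- random:0.002
- random:0.003
- random:0.005
- random:0.01
method: [global]
N: 100
B: 250
alpha: 0.05
seed: 1
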