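# Scenario 3 (Gompertz states 1-2, Weibull state 3) with administrative
# censoring at 90 days; margin threshold 0.0028 plus power thresholds.
scenario: scenario3
n_pairs:
- [200, 200]
- [250, 300]
- [300, 300]
- [250, 450]
- [300, 500]
- [500, 500]
deltas: [0.0028, 0.004, 0.005, 0.007, 0.01]
censoring: administrative:90
method: [global]
N: 100
B: 100
alpha: 0.05
seed: 1
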