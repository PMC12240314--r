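# Swine movement network report

Total heads: 350; intra-state fraction 11.4%; daily permit frequency 0.0 (sd 0.1).
Top-4 supply concentration: 100.0%; top-4 demand concentration: 100.0%.

## Supply ranking
| rank | node | share |
|---|---|---|
| 1 | Jalisco | 54.3% |
| 2 | Puebla | 25.7% |
| 3 | Sonora | 20.0% |

## Demand ranking
| rank | node | share |
|---|---|---|
| 1 | Mexico | 77.1% |
| 2 | Sonora | 14.3% |
| 3 | Jalisco | 8.6% |

## Networks
- `state/all/all`: 4 nodes, 6 links of 16 possible (density 37.5%), avg centrality supply 25.0% / demand 25.0%
- `state/slaughter/all`: 4 nodes, 4 links of 16 possible (density 25.0%), avg centrality supply 18.8% / demand 18.8%

## Conventions
- relative centrality denominator: n_total
- eigenvector prestige computed on: binary matrix
- rest stop at exact journey end counted: false
- seed: 5
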