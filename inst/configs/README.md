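# Full-scale reproduction configurations

These configurations document the full-scale experiments. They are not
run by the test-suite: one replicate of `default_full_scale.yml` is a single
100,000-generation simulation of ~10^9 elementary events, and the complete
factor sweeps below total 50 replicates x 6 factors x ~5 values each —
cluster-scale work.

The grand-average stationary species diversity across all factor sweeps is
expected near 45 species (vs 9 environmental optima), and the grand-average
critical diversity — the diversity at which every species is confined to a
single site, speciation collapses and extinction blows up — near 55.

Sweeps (each holds every other key of `default_full_scale.yml` fixed,
50 replicates per value; the landscape-dynamics sweeps co-adjust `f` and `c`
with `barrier_rates()` so that the complementary summary stays constant):

| factor                     | CLI `--factor` | values                                  |
|----------------------------|----------------|-----------------------------------------|
| genetic incompatibility    | `GIT`          | 4, 8, 15, 20, 25                         |
| competition width          | `sigma_ratio`  | 0.25, 0.4, 0.55, 0.75                    |
| resource abundance         | `K_star`       | 75, 150, 225, 375                        |
| pace of landscape dynamics | `pace`         | 9.9e-6, 2.4e-5, 4.76e-5, 9e-5, 1.4e-4    |
| time in isolation          | `isolation`    | 0.52, 0.75, 0.95, 0.99                   |
| local catastrophe rate     | `cr`           | 0, 1e-4, 2.5e-4, 5e-4                    |

Example:

```sh
Rscript inst/cli/cladesim.R sweep \
  --config inst/configs/default_full_scale.yml \
  --factor sigma_ratio --values 0.25,0.4,0.55,0.75 \
  --replicates 50 --seed 1 --out sweeps/sigma_ratio
```

Runs under high resource abundance or slow landscape dynamics need
`horizon: 200000` (or 300000) to reach stationarity.
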