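# Demo config: guilt-prone basin of attraction vs apology cost (c = d),
# desk-scale sample count. Run with:
#   Rscript inst/cli/meaculpa.R experiment --config inst/extdata/basin_cost_demo.yaml
experiment: basin_cost
p: [0.9, 0.95]
c: [0.005, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0]
samples: 1000
seed: 7
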