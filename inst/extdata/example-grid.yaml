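# Example grid configuration for `run_cli(c("grid", "--config", ...))` /
# read_grid_config(): any design field may be a scalar or a list of values;
# omitted fields use the package defaults.
a3: [0.39, 0.59]
b3: [0.39, 0.59]
c3p: 0.39
icc_m3: [0.1, 0.2]
icc_y2: 0.1
icc_y3: 0.2
n3: [20, 40, 60]
n2: [5, 10]
n1: 6
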