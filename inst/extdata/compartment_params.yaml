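# Example threshold/range parameter file for the rule-based compartment
# stage, consumable by the CLI:  renalseg.R run --params <this file>
# Values are the validated defaults; see ?compartment_params.
delta: 2        # sigmoid gain
mu: 1.5         # sigmoid cut-off on the [0, 1] intensity scale
gamma: 1.5      # gamma exponent for peripheral slices
r_f: 0.3        # first depth-range fraction
r_l: 0.7        # last depth-range fraction
alpha: 30       # lower medulla-percentage bound for temporal fusion
beta: 60        # upper medulla-percentage bound
x: 0.375        # reference-time fraction (t_x = round(x * T))
closing_radius: 2
rim_radius: 1
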