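# Default CANN configuration: 2 CAN streams x 3 layers x 2 CANs, fed by
# 4 RF + 4 LCF inputs and an 8-unit UCF broadcast stream, 1 output neuron;
# 29 neurons in total.
n_streams: 3
n_layers: 3
n_rf_inputs: 4
n_lcf_inputs: 4
n_ucf_units: 8
cans_per_stream_layer: 2
n_outputs: 1
lateral_rule: neighboring-streams-same-layer
ucf_rule: broadcast-to-all-cans
init_weight_scale: 0.1
can_row_mass: 6.0
r_sink_output: 1.0
seed: 0
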