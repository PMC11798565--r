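p_healthy: 0.8
r_healthy: 0.031
p_mdd: 0.079
r_mdd: 0.554
p_bd: 0.004
r_bd: 0.594
tp_fn_ratio: 3.0666667
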