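population,category,cost_annual
adult,overweight,0
adult,obesity1,10
adult,obesity2,139
adult,obesity3,536
child,overweight,8
child,obesity,24
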