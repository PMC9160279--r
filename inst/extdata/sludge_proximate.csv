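component,percent
moisture,6.3
volatile_solid,60.1
ash,27.0
fixed_carbon,6.7
sulfur,0.9
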