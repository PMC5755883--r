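case,method,delta_U,delta_E,delta_R
B01,CFD,56,51,82
B01,MRI,51,53,79
B02,CFD,39,22,75
B02,MRI,11,25,62
A01,CFD,79,79,85
A01,MRI,83,81,87
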