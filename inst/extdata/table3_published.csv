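case,method,U_pre,E_pre,R_pre,U_post,E_post,R_post
B01,CFD,0.089,806,92,0.039,395,16.56
B01,MRI,0.081,2.8,87,0.040,1.32,18.27
B02,CFD,0.075,929,89,0.045,724,22.25
B02,MRI,0.071,14.9,79,0.063,11.8,30.02
A01,CFD,0.416,2818,74,0.087,592,11.1
A01,MRI,0.443,18.4,81,0.076,3.5,10.53
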