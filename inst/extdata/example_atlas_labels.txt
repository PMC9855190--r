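Precentral_L
Precentral_R
Rolandic_Oper_R
Supp_Motor_Area_L
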