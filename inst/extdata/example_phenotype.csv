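SUB_ID,DX_GROUP,SITE_ID,AGE_AT_SCAN,SEX,FIQ
sub001,1,NYU,17.7,1,105
sub002,2,NYU,21.0,2,118
sub003,1,UCLA,9.3,1,
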