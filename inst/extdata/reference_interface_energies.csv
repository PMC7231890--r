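sequence,class,dg_c,se_c,dg_zip,se_zip
ILQINS,1,-28.1,0.2,-18.6,0.1
ILQINS,5,-28.9,0.2,-16.3,0.2
IFQINS,1,-27.1,0.1,-20.5,0.1
IFQINS,5,-29.3,0.2,-16.4,0.3
TFQINS,1,-26.1,0.1,-21.7,0.2
TFQINS,5,-29.5,0.2,-13.1,0.2
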