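roi,channel
LFOA,CH02
LFOA,CH03
LFOA,CH04
LFOA,CH10
LFOA,CH11
RFOA,CH04
RFOA,CH05
RFOA,CH06
RFOA,CH12
RFOA,CH13
LOFA,CH18
LOFA,CH19
ROFA,CH19
ROFA,CH20
LPTBA,CH08
RPTBA,CH15
LDLPFC,CH01
LDLPFC,CH09
LDLPFC,CH17
RDLPFC,CH07
RDLPFC,CH14
RDLPFC,CH21
LIPFG,CH16
RIPFG,CH22
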