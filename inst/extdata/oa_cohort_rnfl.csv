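case,affected_rnfl_um,nonaffected_rnfl_um
1,51,113
2,60,108
3,37,109
4,62,105
5,48,103
6,41,121
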