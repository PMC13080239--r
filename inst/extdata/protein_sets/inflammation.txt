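B2m
C3
C1qa
C1qb
C1qc
Cd68
Lgals3
S100a8
S100a9
Anxa1
Ptx3
Lcn2
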