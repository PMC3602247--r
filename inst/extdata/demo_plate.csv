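# synthetic demo plate, allelic-discrimination (SDS) dialect
Well,Sample Name,Marker,Call
A1,S001,rs328,rs328_G
A2,S002,rs328,rs328_C
A3,S003,rs328,Both
A4,S004,rs328,Both
A5,S005,rs328,rs328_G
A6,S006,rs328,rs328_G
A7,S007,rs328,Undetermined
A8,S008,rs328,Both
A9,S002,rs328,rs328_C
A10,NTC,rs328,Undetermined
A11,S009,rs328,rs328_G
A12,S010,rs328,rs328_G
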