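# synthetic demo manifest
S001
S002
S003
S004
S005
S006
S007
S008
S009
S010
S011
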