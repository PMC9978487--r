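region,n,area_pct
global,61425,100
NH,6729,11
NI,4814,8
LL,24070,39
SI,8566,14
SO,17246,28
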