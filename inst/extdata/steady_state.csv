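gene,experimental
lexA,11.471
recA,11.795
recF,8.975
rpoS,10.383
rpoD,9.4618
umuDC,7.8192
dinI,9.9169
ssB,10.213
rpoH,8.5983
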