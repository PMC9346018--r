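index,healthy,preop,f05,f10,f15
tilt,12,18,9,7,5
bisect_offset,48.5,76,65,58,53
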