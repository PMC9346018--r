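group,mean,sd
healthy,640,96.4
preop,598.1,37.6
postop,478.4,57.2
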