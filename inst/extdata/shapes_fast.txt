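1011100111001011
101101111111
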