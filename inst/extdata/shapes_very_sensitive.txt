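1010001101000011
1000110011100001
1100000000111101
1011110010001
111010111
1110000101101
1001010001011001
111001000011001
1100010110000011
100100011011001
10010110101001
10101010000111
1101100111
1011010100011
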