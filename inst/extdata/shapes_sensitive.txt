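101101000101011
100111110011
1100011011000011
10000101111101
11110101011
1010110111000001
111000111000011
110110001001101
1001001011110001
101110110000101
1100000100110111
101010001110101
1110011001011
1011000010011101
1111011011
1110101010101
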