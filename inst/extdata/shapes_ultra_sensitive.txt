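11011010011
1001110000001011
111000101000011
1001000110010011
1000100001110101
110000000110111
101000111011
1110010001000101
10010110101001
10111010101
100110100010101
101111011
10001010111001
10110010100101
10011100111
1100111101
1111000011001
11100110011
100110110100001
100101010101001
101100011000011
101001001001011
10011100001011
10011111001
100000111000111
10110010010011
1010010011011
1101101000000101
11101001101
100100010110011
10000011011011
1110010111
100000110111001
11001010001011
110010100100101
1100001101011
1001000101001101
111101000000011
11010011101
1000111000010011
100100101111
1000011100011001
1011000001000111
1010010101010001
1010001011000101
10010001110101
101010000010111
11110100101
101100000111001
1001100100111
111011000101
1111000100000101
1110000100101001
1000110100100101
1001011001010001
1010100000111001
110010001111
1011010000101001
1110101001000001
11100110000101
111000001011001
110011000110001
1010110000100011
11010101011
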