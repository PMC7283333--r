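gene_id,word
gene01,1111000000000000
gene02,1100110000000000
gene03,1100001100000000
gene04,1100000011000000
gene05,1100000000110000
gene06,1100000000001100
gene07,1100000000000011
gene08,1010101000000000
gene09,1010010100000000
gene10,1010000010100000
gene11,1010000001010000
gene12,1010000000001010
gene13,1010000000000101
gene14,1001100100000000
gene15,1001011000000000
gene16,1001000010010000
gene17,1001000001100000
gene18,1001000000001001
gene19,1001000000000110
gene20,1000100010001000
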