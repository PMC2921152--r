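ID SYN_GATA_like
XX
P0      A      C      G      T
01      2      1      1     16
02      1      1     17      1
03     18      1      0      1
04      1      1      1     17
05     16      1      2      1
06     10      3      4      3
XX
//
ID SYN_HOX_like
XX
P0      A      C      G      T
01      3      2      2     13
02     16      1      2      1
03     17      1      1      1
04      1      1      1     17
05      2      2     12      4
06      6      4      6      4
XX
//
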