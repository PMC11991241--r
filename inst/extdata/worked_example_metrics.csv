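level,TC,TM,OH
1,29,0,3
2,54,6,3
3,76,10,8
4,91,27,11
5,98,44,20
6,115,57,21
7,115,89,31
8,111,119,34
9,128,139,42
10,131,161,57
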