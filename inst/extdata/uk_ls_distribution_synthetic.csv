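ls_range,share,representative_ls
0-4,0.06,2
5-6,0.10,5.5
7-8,0.50,7.5
9-10,0.34,9.5
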