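timepoint_hr	n_cells
0	9191
1	9460
4	9865
16	5165
27	7678
36	10119
48	11809
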