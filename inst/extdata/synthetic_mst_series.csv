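"ligand_uM","signal"
29.6,901.562111397329
14.8,882.392317471566
7.4,903.460491823927
3.7,908.89247360789
1.85,864.928833714109
0.925,853.64167007845
0.4625,809.137829402982
0.23125,830.264208983572
0.115625,810.689050738044
0.0578125,788.346929954711
0.02890625,830.420871343198
0.014453125,782.469042988721
0.0072265625,811.144000857382
0.00361328125,794.443405499163
0.001806640625,790.576845377255
0.0009033203125,800.9597365973
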