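volunteer,scenario,amplitude_mean_mm,amplitude_sd_mm,drift_mean_mm_s,drift_sd_mm_s
1,audio,4.2,0.7,-0.3,0.1
2,audio,5.0,1.2,-0.5,0.1
3,audio,23.8,1.3,-0.5,0.4
4,audio,21.0,0.8,-0.0,0.3
5,audio,13.1,0.2,-0.4,0.1
6,audio,13.1,2.8,-0.6,0.1
7,audio,6.8,0.8,-0.0,0.1
8,audio,17.0,0.7,-1.0,0.1
9,audio,10.3,0.6,-0.3,0.2
10,audio,11.6,1.6,-0.0,0.1
1,visual,10.9,0.2,-0.2,0.0
2,visual,10.5,0.2,-0.2,0.1
3,visual,16.7,0.4,-0.0,0.0
4,visual,12.7,0.5,-0.5,0.2
5,visual,12.1,1.0,-0.2,0.0
6,visual,11.1,0.3,-0.2,0.3
7,visual,10.3,1.8,-0.4,0.1
8,visual,10.9,0.2,-0.2,0.0
9,visual,4.8,0.1,0.0,0.1
10,visual,9.5,0.4,0.1,0.0
1,visual_table,14.4,0.4,-0.1,0.2
2,visual_table,18.2,0.1,-0.3,0.2
3,visual_table,18.2,0.7,-0.2,0.2
4,visual_table,17.1,0.2,-0.4,0.0
5,visual_table,15.4,0.7,-0.4,0.0
6,visual_table,19.3,0.7,-0.4,0.4
7,visual_table,6.9,0.2,0.0,0.1
8,visual_table,11.6,0.2,-0.1,0.2
9,visual_table,9.5,0.7,-0.2,0.6
10,visual_table,18.8,0.3,0.1,0.1
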