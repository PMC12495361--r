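volunteer,scenario,amplitude_mean_mm,amplitude_sd_mm,duration_mean_s,duration_sd_s
1,audio,14.4,0.7,4.4,0.2
2,audio,8.1,1.3,3.0,0.2
3,audio,41.0,2.8,4.5,0.3
4,audio,11.7,1.0,5.7,1.6
5,audio,8.2,0.9,4.1,0.2
6,audio,12.1,1.1,5.3,0.4
7,audio,14.7,0.9,7.9,0.2
8,audio,14.4,0.4,5.6,0.5
9,audio,20.6,1.8,4.8,0.4
10,audio,16.9,1.7,9.7,0.9
1,visual,27.5,3.0,9.7,1.8
2,visual,32.4,1.8,9.7,0.7
3,visual,32.9,1.3,10.0,0.3
4,visual,31.7,2.5,9.9,0.7
5,visual,15.1,7.6,6.8,3.0
6,visual,30.0,2.1,11.3,1.9
7,visual,30.4,2.3,9.9,0.0
8,visual,31.9,2.5,9.4,2.2
9,visual,31.2,2.3,10.1,1.7
10,visual,27.6,2.4,10.3,1.0
1,visual_table,30.2,3.6,8.4,2.9
2,visual_table,30.7,2.4,9.9,0.6
3,visual_table,33.6,1.7,10.0,0.2
4,visual_table,30.5,1.6,9.9,0.4
5,visual_table,25.2,1.3,9.9,0.3
6,visual_table,29.0,1.5,9.9,0.3
7,visual_table,29.9,1.6,10.0,0.2
8,visual_table,26.1,2.7,9.3,1.4
9,visual_table,30.8,2.8,9.8,1.0
10,visual_table,35.4,2.4,10.3,0.6
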