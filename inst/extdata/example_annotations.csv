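"leaf_id","genotype","trichome_id","x_px","y_px","class"
"example1","wt",1,33.8977454532869,18.6156977787614,1
"example1","wt",2,42.7437493905891,7.29201042582281,1
"example1","wt",3,61.4720625006594,22.665855484549,1
"example1","wt",4,51.7314771017991,24.2728119457606,2
"example1","wt",5,18.9534477700945,33.5847007129341,2
"example1","wt",6,48.7952232353855,33.496703693876,2
"example1","wt",7,62.5656457394361,52.1270387584809,3
"example1","wt",8,17.8622208475135,59.179993461119,3
"example1","wt",9,33.3470243921038,71.99807613343,4
"example1","wt",10,49.3384638719726,67.9569038648624,4
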