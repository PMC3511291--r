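subject,peep_cmH2O,top_cmH2O,tcp_cmH2O
1,5,42.4,9.6
1,10,39.2,13.4
1,15,32.9,16.6
1,20,27.2,19.8
2,5,36.3,8.2
2,10,40.0,13.5
2,15,33.8,16.8
2,20,29.3,20.4
3,5,44.6,10.2
3,10,37.4,13.2
3,15,32.2,16.4
3,20,25.1,19.7
4,5,39.0,10.4
4,10,33.9,13.7
4,15,29.0,16.6
4,20,19.2,19.0
5,5,42.6,10.2
5,10,32.7,13.2
5,15,24.8,15.7
5,20,19.2,18.4
6,5,31.3,9.03
6,10,28.1,12.5
6,15,23.8,15.5
6,20,21.5,18.8
7,5,47.7,11.1
7,10,40.8,14.6
7,15,34.1,17.2
7,20,27.0,19.6
8,5,46.0,10.6
8,10,40.2,13.4
8,15,33.4,16.6
8,20,27.9,19.5
9,5,38.2,8.7
9,10,33.9,12.3
9,15,29.4,15.8
9,20,22.8,19.3
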