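subject,peep_cmH2O,top_cmH2O,tcp_cmH2O
5,5,48.1,10.2
5,10,44.1,14.0
5,15,33.3,16.7
5,20,22.7,19.0
6,5,49.5,10.2
6,10,41.6,13.7
6,15,31.1,16.7
6,20,19.1,18.9
9,5,68.1,9.6
9,10,64.7,14.1
9,15,58.7,18.2
9,20,49.4,21.8
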