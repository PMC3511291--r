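subject,state,limb,sd_cmH2O
5,healthy,inflation,23
5,healthy,deflation,4
5,ards,inflation,25
5,ards,deflation,4
6,healthy,inflation,14
6,healthy,deflation,3
6,ards,inflation,25
6,ards,deflation,4
9,healthy,inflation,21
9,healthy,deflation,3
9,ards,inflation,23
9,ards,deflation,3
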