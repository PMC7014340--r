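measured,modelled,count
High,Moderate,7
High,Good,19
High,High,146
Good,Moderate,13
Good,Good,21
Good,High,53
Moderate,Bad,1
Moderate,Poor,2
Moderate,Moderate,6
Moderate,Good,14
Moderate,High,22
Poor,Bad,3
Poor,Poor,1
Poor,Moderate,2
Poor,Good,5
Poor,High,4
Bad,Bad,1
Bad,Poor,2
Bad,Good,1
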