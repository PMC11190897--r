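mediator	receptor
Agt	Agtr1a
Agt	Agtr1b
Il1b	Il1r1
Osm	Osmr
Il17a	Il17ra
Cxcl1	Cxcr2
Cxcl3	Cxcr2
Ccl11	Ccr3
Ccl24	Ccr3
Il19	Il20ra
Il23a	Il23r
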