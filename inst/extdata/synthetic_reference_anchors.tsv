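name	start	end
CSR6	151	159
CSR1	195	200
CSR5	256	260
WW	271	272
CSR2	285	293
CSR3	322	329
CSR4	385	390
CSR7	416	424
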