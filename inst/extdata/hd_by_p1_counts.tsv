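p1_is_d	octamer_hd	n
TRUE	0	346816
TRUE	1	111584
TRUE	2	57620
TRUE	3	27071
TRUE	4	12265
TRUE	5	5380
TRUE	6	1750
TRUE	7	286
FALSE	1	8894
FALSE	2	11338
FALSE	3	10704
FALSE	4	7816
FALSE	5	5074
FALSE	6	2650
FALSE	7	978
FALSE	8	201
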