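model_id	rmsd_A	dope
1	1.14	-227166
2	1.05	-226840
3	1.01	-227057
4	1.09	-226705
5	1.09	-225611
6	1.13	-227439
7	1.15	-226287
8	1.05	-229642
9	1.11	-227128
10	1.07	-226868
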