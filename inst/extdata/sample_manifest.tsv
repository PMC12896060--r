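sample_type	group	y2017	y2018	y2019
air	Denver	28	3	7
air	Hong Kong	80	79	80
air	London	41	36	40
air	New York	29	48	48
air	Oslo	64	63	64
air	Stockholm	8	32	0
field_negative	all	4	3	3
lab_negative	all	4	4	4
positive	all	2	2	1
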