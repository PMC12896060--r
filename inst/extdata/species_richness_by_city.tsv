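city	Bacteria	Fungi	Virus	Archaea
All	2560	956	36	25
Denver	776	199	2	3
Hong Kong	1931	653	14	12
London	836	276	4	16
New York	1237	413	8	15
Oslo	969	442	11	7
Stockholm	590	213	2	6
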