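species	cross	offspring	map_cM
melpomene	1	111	1048
melpomene	2	122	1065
melpomene	3	102	1135
cydno	1	95	1076
cydno	2	77	1076
cydno	3	125	1070
hybrid	1	170	1090
hybrid	2	88	1069
hybrid	3	68	1158
hybrid	4	5	1040
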