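tract	hemisphere	x	y	z
AC	left	-6	0	-7
AC	right	8	1	-7
Splenium	left	-4	-36	15
Splenium	right	4	-36	16
Cingulum	left	-12	-48	8
Cingulum	right	15	-46	8
AF	left	-33	-2	26
AF	right	32	0	23
MdLF	left	-17	-57	43
MdLF	right	21	-54	44
EmC	left	-27	10	-11
EmC	right	29	10	-10
Occ	left	-30	-72	5
Occ	right	32	-72	6
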