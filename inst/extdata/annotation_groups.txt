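# WFDB annotation codes and their grouping into the 15-label beat vocabulary.
# Columns: code  symbol  is_beat  grouped
# Beat symbols outside the 14 named beat classes group to "Q" (unclassifiable
# beat); every non-beat symbol groups to "Z".
1	N	1	N
2	L	1	L
3	R	1	R
4	a	1	a
5	V	1	V
6	F	1	F
7	J	1	J
8	A	1	A
9	S	1	S
10	E	1	E
11	j	1	j
12	/	1	Q
13	Q	1	Q
14	~	0	Z
16	|	0	Z
18	s	0	Z
19	T	0	Z
20	*	0	Z
21	D	0	Z
22	"	0	Z
23	=	0	Z
24	p	0	Z
25	B	1	Q
26	^	0	Z
27	t	0	Z
28	+	0	Z
29	u	0	Z
30	?	0	Z
31	!	0	Z
32	[	0	Z
33	]	0	Z
34	e	1	e
35	n	1	Q
36	@	0	Z
37	x	0	Z
38	f	1	f
39	(	0	Z
40	)	0	Z
41	r	1	Q
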