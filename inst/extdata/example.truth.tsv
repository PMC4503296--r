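site	h1	h2	err_h1	err_h2	is_error
1	A	T	A	T	0
2	C	G	C	G	0
3	T	G	T	G	0
4	G	A	G	A	0
5	T	C	T	C	0
6	C	A	C	A	0
7	T	A	T	A	0
8	G	A	G	A	0
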