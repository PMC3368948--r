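#nodes
1	-0.5	-0.8660254037844386
2	0.5	-0.8660254037844386
3	-1	0
4	0	0
5	1	0
6	-0.5	0.8660254037844386
7	0.5	0.8660254037844386
#links
1	2	9
3	4	4
4	5	7
6	7	1
1	4	2
2	5	5
3	6	3
4	7	8
1	3	6
2	4	11
4	6	12
5	7	10
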