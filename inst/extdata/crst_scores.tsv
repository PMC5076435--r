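subject_id	session_id	posture	action
1	pre	2	2
2	pre	1	3
3	pre	3	3
4	pre	2	3
5	pre	2	3
6	pre	3	4
7	pre	1	2
8	pre	3	3
1	post7d	2	2
2	post7d	0	0
3	post7d	0	1
4	post7d	1	1
5	post7d	0	0
6	post7d	0	2
7	post7d	0	0
8	post7d	0	1
1	post3m	1	2
2	post3m	0	0
3	post3m	2	2
4	post3m	1	1
5	post3m	0	0
6	post3m	1	2
7	post3m	0	0
8	post3m	0	0
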