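query_id	length
Q0001	100
Q0002	101
Q0003	102
Q0004	103
Q0005	104
Q0006	105
Q0007	106
Q0008	107
Q0009	108
Q0010	109
Q0011	110
Q0012	111
Q0013	112
Q0014	113
Q0015	114
Q0016	115
Q0017	116
Q0018	117
Q0019	118
Q0020	119
Q0021	120
Q0022	121
Q0023	122
Q0024	123
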