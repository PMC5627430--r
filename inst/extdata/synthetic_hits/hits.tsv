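Q0001	S01|hit_Q0001	80.0	100	10	1	1	100	1	100	1e-50	500
Q0002	S01|hit_Q0002	80.0	101	10	1	1	101	1	101	1e-50	500
Q0003	S01|hit_Q0003	80.0	102	10	1	1	102	1	102	1e-50	500
Q0003	S01|decoy_Q0003	30.0	30	50	5	1	30	1	30	1e-3	40
Q0004	S01|hit_Q0004	80.0	103	10	1	1	103	1	103	1e-50	500
Q0005	S01|hit_Q0005	80.0	104	10	1	1	104	1	104	1e-50	500
Q0006	S01|hit_Q0006	80.0	105	10	1	1	105	1	105	1e-50	500
Q0006	S01|decoy_Q0006	30.0	31	50	5	1	31	1	31	1e-3	40
Q0008	S01|hit_Q0008	80.0	107	10	1	1	107	1	107	1e-50	500
Q0009	S01|hit_Q0009	80.0	108	10	1	1	108	1	108	1e-50	500
Q0009	S01|decoy_Q0009	30.0	32	50	5	1	32	1	32	1e-3	40
Q0011	S01|hit_Q0011	80.0	110	10	1	1	110	1	110	1e-50	500
Q0012	S01|hit_Q0012	80.0	111	10	1	1	111	1	111	1e-50	500
Q0012	S01|decoy_Q0012	30.0	33	50	5	1	33	1	33	1e-3	40
Q0013	S01|hit_Q0013	80.0	112	10	1	1	112	1	112	1e-50	500
Q0014	S01|hit_Q0014	80.0	113	10	1	1	113	1	113	1e-50	500
Q0015	S01|decoy_Q0015	30.0	34	50	5	1	34	1	34	1e-3	40
Q0017	S01|hit_Q0017	80.0	116	10	1	1	116	1	116	1e-50	500
Q0018	S01|decoy_Q0018	30.0	35	50	5	1	35	1	35	1e-3	40
Q0019	S01|hit_Q0019	80.0	118	10	1	1	118	1	118	1e-50	500
Q0020	S01|hit_Q0020	80.0	119	10	1	1	119	1	119	1e-50	500
Q0021	S01|hit_Q0021	80.0	120	10	1	1	120	1	120	1e-50	500
Q0021	S01|decoy_Q0021	30.0	36	50	5	1	36	1	36	1e-3	40
Q0022	S01|hit_Q0022	80.0	121	10	1	1	121	1	121	1e-50	500
Q0024	S01|hit_Q0024	80.0	123	10	1	1	123	1	123	1e-50	500
Q0024	S01|decoy_Q0024	30.0	36	50	5	1	36	1	36	1e-3	40
Q0002	S02|hit_Q0002	80.0	101	10	1	1	101	1	101	1e-50	500
Q0003	S02|hit_Q0003	80.0	102	10	1	1	102	1	102	1e-50	500
Q0003	S02|decoy_Q0003	30.0	30	50	5	1	30	1	30	1e-3	40
Q0005	S02|hit_Q0005	80.0	104	10	1	1	104	1	104	1e-50	500
Q0006	S02|decoy_Q0006	30.0	31	50	5	1	31	1	31	1e-3	40
Q0008	S02|hit_Q0008	80.0	107	10	1	1	107	1	107	1e-50	500
Q0009	S02|hit_Q0009	80.0	108	10	1	1	108	1	108	1e-50	500
Q0009	S02|decoy_Q0009	30.0	32	50	5	1	32	1	32	1e-3	40
Q0012	S02|hit_Q0012	80.0	111	10	1	1	111	1	111	1e-50	500
Q0012	S02|decoy_Q0012	30.0	33	50	5	1	33	1	33	1e-3	40
Q0013	S02|hit_Q0013	80.0	112	10	1	1	112	1	112	1e-50	500
Q0015	S02|decoy_Q0015	30.0	34	50	5	1	34	1	34	1e-3	40
Q0016	S02|hit_Q0016	80.0	115	10	1	1	115	1	115	1e-50	500
Q0018	S02|decoy_Q0018	30.0	35	50	5	1	35	1	35	1e-3	40
Q0021	S02|hit_Q0021	80.0	120	10	1	1	120	1	120	1e-50	500
Q0021	S02|decoy_Q0021	30.0	36	50	5	1	36	1	36	1e-3	40
Q0022	S02|hit_Q0022	80.0	121	10	1	1	121	1	121	1e-50	500
Q0023	S02|hit_Q0023	80.0	122	10	1	1	122	1	122	1e-50	500
Q0024	S02|hit_Q0024	80.0	123	10	1	1	123	1	123	1e-50	500
Q0024	S02|decoy_Q0024	30.0	36	50	5	1	36	1	36	1e-3	40
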