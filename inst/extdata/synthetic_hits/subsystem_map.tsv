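query_id	subsystem
Q0001	subsys_1
Q0002	subsys_2
Q0003	subsys_3
Q0004	subsys_1
Q0005	subsys_2
Q0006	subsys_3
Q0007	subsys_1
Q0008	subsys_2
Q0009	subsys_3
Q0010	subsys_1
Q0011	subsys_2
Q0012	subsys_3
Q0013	subsys_1
Q0014	subsys_2
Q0015	subsys_3
Q0016	subsys_1
Q0017	subsys_2
Q0018	subsys_3
Q0019	subsys_1
Q0020	subsys_2
Q0021	subsys_3
Q0022	subsys_1
Q0023	subsys_2
Q0024	subsys_3
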