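gene	term_id	stage_id	record_id
gene9091	XAOT:0000018	XAOT:1000041	XB-IMG-0001
gene5403	XAOT:0000017	XAOT:1000037	XB-IMG-0002
gene0932	XAOT:0000018	XAOT:1000044	XB-IMG-0003
gene9189	XAOT:0000006	XAOT:1000033	XB-IMG-0004
gene5637	XAOT:0000003	XAOT:1000063	XB-IMG-0005
gene4002	XAOT:0000002	XAOT:1000058	XB-IMG-0006
gene9052	XAOT:0000010	XAOT:1000040	XB-IMG-0007
gene0259	XAOT:0000007	XAOT:1000043	XB-IMG-0008
gene5434	XAOT:0000017	XAOT:1000050	XB-IMG-0009
gene0481	XAOT:0000004	XAOT:1000030	XB-IMG-0010
gene7326	XAOT:0000009	XAOT:1000041	XB-IMG-0011
gene8491	XAOT:0000009	XAOT:1000040	XB-IMG-0012
gene2454	XAOT:0000003	XAOT:1000038	XB-IMG-0013
gene9028	XAOT:0000016	XAOT:1000060	XB-IMG-0014
gene9174	XAOT:0000014	XAOT:1000037	XB-IMG-0015
gene7789	XAOT:0000002	XAOT:1000024	XB-IMG-0016
gene5468	XAOT:0000017	XAOT:1000029	XB-IMG-0017
gene6341	XAOT:0000007	XAOT:1000056	XB-IMG-0018
gene9732	XAOT:0000008	XAOT:1000059	XB-IMG-0019
gene2274	XAOT:0000008	XAOT:1000057	XB-IMG-0020
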