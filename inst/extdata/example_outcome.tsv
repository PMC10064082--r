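SNP	EA	OA	EAF	BETA	SE	P	N
rs000001	C	A	0.5356	-0.0779357	0.00188876	2.22507e-308	563946
rs000002	T	G	0.4746	0.0202895	0.00188623	5.5133e-27	563946
rs000004	A	C	0.4214	-0.0211536	0.00190552	1.23727e-28	563946
rs000005	A	T	0.3344	-0.0716463	0.00198945	5.21145e-284	563946
rs000006	A	G	0.2781	-0.115765	0.002089	2.22507e-308	563946
rs000007	T	G	0.389	0.0729957	0.00193846	2.22507e-308	563946
rs000008	T	C	0.8907	0.0401782	0.0030022	7.6115e-41	563946
rs000009	G	A	0.6548	0.0251576	0.0019799	5.44337e-37	563946
rs000010	A	G	0.6321	0.0434872	0.00195327	8.28642e-110	563946
rs000011	A	C	0.25	0.0310057	0.00215759	7.92075e-47	563946
rs000012	T	C	0.3705	-0.124701	0.00194642	2.22507e-308	563946
rs000103	A	G	0.8251	0.118384	0.0024575	2.22507e-308	563946
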