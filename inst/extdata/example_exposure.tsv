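SNP	EA	OA	EAF	BETA	SE	P	N
rs000001	C	A	0.5383	-0.135762	0.00364996	8.11780999999999e-303	151013
rs000002	T	G	0.4717	0.0338417	0.00364507	1.62843e-20	151013
rs000003	A	G	0.8212	0.232101	0.00474903	2.22507e-308	151013
rs000004	C	A	0.5763	0.0277548	0.00368234	4.799e-14	151013
rs000005	A	T	0.3388	-0.134105	0.00384454	1.40109e-266	151013
rs000006	A	G	0.2836	-0.22035	0.00403692	2.22507e-308	151013
rs000007	T	G	0.3815	0.124978	0.00374601	4.71868e-244	151013
rs000008	T	C	0.8894	0.0789715	0.00580165	3.4029e-42	151013
rs000009	G	A	0.6544	0.0415989	0.00382609	1.55998e-27	151013
rs000010	A	G	0.6327	0.0768436	0.00377462	3.94753e-92	151013
rs000011	A	C	0.256	0.0602205	0.00416947	2.76605e-47	151013
rs000012	C	T	0.6264	0.227197	0.00376139	2.22507e-308	151013
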