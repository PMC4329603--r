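# Synthetic stand-in cleavage-site scoring matrix
# Built by ASAFindR buildMatrix() from synthetic_training_windows.tsv
# (500 windows sampled from defaultCleavagePWM at seed 42, no correction).
# SYNTHETIC stand-in; not a published matrix.
residue	-5	-4	-3	-2	-1	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20
A	0.099281	0.031413	1.979420	0.074105	1.778571	0.019972	1.144227	0.175932	0.072550	0.074998	0.081464	0.083109	0.094833	0.082414	0.093938	0.109610	0.098529	0.089639	0.072268	0.087350	0.071618	0.092351	0.080921	0.063625	0.071221
C	0.003365	0.003366	0.005182	0.004117	0.014539	0.000000	0.014670	0.006067	0.006148	0.008490	0.008511	0.016930	0.004516	0.009778	0.004336	0.003272	0.003340	0.007114	0.005668	0.002730	0.008952	0.007570	0.006526	0.008676	0.003815
D	0.023558	0.020194	0.031090	0.037052	0.033924	0.000000	0.029339	0.018200	0.008608	0.005660	0.009727	0.007695	0.006021	0.004191	0.008671	0.011452	0.006680	0.002846	0.002834	0.008189	0.007673	0.009084	0.006526	0.002892	0.007631
E	0.020193	0.023560	0.025909	0.049403	0.029077	0.019972	0.055011	0.039433	0.004919	0.008490	0.007295	0.009234	0.007526	0.002794	0.002890	0.001636	0.005010	0.004269	0.008502	0.008189	0.006394	0.001514	0.009136	0.007230	0.007631
F	0.028606	0.026926	0.010363	0.028818	0.029077	2.842704	0.033007	0.015167	0.017215	0.021226	0.014590	0.015391	0.015053	0.008381	0.010116	0.009816	0.015030	0.014228	0.014170	0.013648	0.015347	0.010598	0.010441	0.021690	0.015262
G	0.035337	0.031413	0.036272	0.028818	0.058155	0.019972	0.069681	0.054599	0.023364	0.028301	0.029181	0.024625	0.031611	0.032127	0.026014	0.029447	0.030060	0.022765	0.032591	0.021837	0.019183	0.022709	0.039155	0.020244	0.025436
H	0.013462	0.010097	0.015545	0.008234	0.009692	0.000000	0.025672	0.009100	0.009837	0.009905	0.004863	0.007695	0.007526	0.008381	0.010116	0.008180	0.003340	0.009960	0.008502	0.010919	0.005116	0.001514	0.006526	0.011568	0.005087
I	0.021875	0.019072	0.031090	0.020585	0.033924	0.006657	0.044009	0.042466	0.017215	0.028301	0.018238	0.018469	0.022579	0.020953	0.014452	0.016360	0.030060	0.019920	0.014170	0.021837	0.021741	0.018167	0.013052	0.028920	0.019077
K	0.023558	0.020194	0.056999	0.053520	0.048462	0.000000	0.029339	0.039433	0.066402	0.100469	0.063225	0.081570	0.081286	0.062858	0.085267	0.096522	0.058449	0.091062	0.056680	0.058688	0.070339	0.090837	0.073090	0.080977	0.076308
L	0.254091	0.089752	0.062181	0.069988	0.072694	0.186407	0.033007	0.057633	0.034431	0.032546	0.035260	0.026164	0.036127	0.029334	0.040466	0.032719	0.043419	0.038417	0.024089	0.036851	0.034530	0.037849	0.027409	0.030366	0.034339
M	0.016827	0.002244	0.015545	0.016468	0.019385	0.006657	0.014670	0.012133	0.004919	0.005660	0.004863	0.006156	0.010537	0.012572	0.008671	0.009816	0.011690	0.007114	0.007085	0.008189	0.003837	0.006056	0.010441	0.005784	0.008903
N	0.023558	0.011219	0.025909	0.037052	0.048462	0.006657	0.044009	0.036400	0.015986	0.014151	0.014590	0.023086	0.019569	0.020953	0.018788	0.004908	0.013360	0.014228	0.017004	0.025932	0.024299	0.028765	0.020883	0.011568	0.013990
P	0.026924	0.020194	0.051817	0.041169	0.029077	0.013315	0.033007	0.794725	0.015986	0.008490	0.019454	0.016930	0.012042	0.018159	0.014452	0.032719	0.021710	0.031303	0.024089	0.012284	0.016626	0.031793	0.019578	0.021690	0.016533
Q	0.015144	0.010097	0.036272	0.020585	0.038770	0.000000	0.044009	0.039433	0.009837	0.015566	0.010943	0.006156	0.018064	0.018159	0.013007	0.013088	0.016700	0.008537	0.011336	0.013648	0.010231	0.028765	0.007831	0.017352	0.022892
R	0.023558	0.022438	0.025909	0.045286	0.024231	0.013315	0.029339	0.030333	0.060254	0.089149	0.063225	0.098500	0.091823	0.088001	0.078041	0.096522	0.100199	0.076834	0.093523	0.081891	0.085686	0.074184	0.067869	0.080977	0.066133
S	0.026924	0.024682	0.062181	1.370933	0.053309	0.006657	0.051344	0.021233	0.116818	0.133016	0.103349	0.170836	0.159561	0.162034	0.134404	0.179957	0.227117	0.145130	0.133199	0.148768	0.121495	0.163507	0.127908	0.169185	0.119549
T	0.033654	0.057217	0.041454	0.028818	0.014539	0.006657	0.047676	0.042466	0.073780	0.082073	0.077816	0.109273	0.096339	0.071239	0.102609	0.089978	0.086839	0.078256	0.113361	0.068242	0.066502	0.095379	0.073090	0.089653	0.080123
V	0.134618	0.117800	0.056999	0.069988	0.063001	0.013315	0.069681	0.042466	0.040579	0.032546	0.027965	0.033859	0.022579	0.025143	0.033240	0.049079	0.045089	0.029880	0.051012	0.039580	0.034530	0.019681	0.039155	0.037597	0.029251
W	0.001683	0.005610	0.005182	0.028818	0.000000	0.026630	0.007335	0.009100	0.003689	0.002830	0.002432	0.004617	0.001505	0.006984	0.002890	0.003272	0.010020	0.007114	0.004251	0.002730	0.006394	0.004542	0.005221	0.004338	0.002544
Y	0.015144	0.013463	0.015545	0.024702	0.024231	0.139805	0.014670	0.030333	0.012297	0.005660	0.010943	0.009234	0.013548	0.013968	0.020233	0.019632	0.008350	0.012806	0.014170	0.010919	0.008952	0.012112	0.007831	0.008676	0.010174
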