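fetal_anomalies	fetal_anomalies	G0001	G0002	G0003	G0004	G0005	G0006	G0007	G0008	G0009	G0010	G0011	G0012	G0013	G0014	G0015
prematurity	prematurity	G0016	G0017	G0018	G0019	G0020	G0021	G0022	G0023
stillbirth	stillbirth	G0024	G0025	G0026	G0027	G0028	G0029
iugr	iugr	G0005	G0030	G0031	G0032	G0033	G0034	G0035
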