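kidney_cancer_dev	synthetic demo set aligned to the planted burden genes	g042	g057	g003	g011	g027	g058	g071	g088	g095
carcinoma_dev	synthetic demo set partially overlapping the planted genes	g042	g005	g019	g033	g047	g061	g076	g090	g099
unrelated_process	synthetic background set	g002	g008	g014	g021	g029	g036	g044	g052	g059	g066	g073	g081	g087	g093
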