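sample_id	population	total_reads	mapping_rate	average_depth	coverage_1x	coverage_4x	coverage_10x
AB01	fast	315216417	98.55	17.46	99.59	99.32	93.57
AB02	fast	282990429	98.49	15.82	99.56	99.24	89.18
AB03	fast	312280472	98.49	16.93	99.52	98.98	90.17
AB04	fast	320340217	98.22	18.25	99.57	99.15	93.1
WS01	slow	326298749	98.6	17.63	99.54	99.25	94.36
WS02	slow	350423462	98.41	19.65	99.57	99.24	94.72
WS03	slow	299507485	98.63	16.45	99.51	99.16	92.2
WS04	slow	315038236	98.52	17.28	99.51	98.98	91.77
WS05	slow	334519623	98.65	18.19	99.54	99.24	95.43
WS06	slow	298331035	98.52	16.88	99.53	99.23	92.89
WS07	slow	227540381	97.88	12.85	99.56	98.73	68.52
WS08	slow	296433759	97.97	16.75	99.61	99.32	90.53
WS09	slow	291390679	98	16.44	99.51	99.18	88.97
WS10	slow	245088985	98.13	13.85	99.6	99.05	76.55
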