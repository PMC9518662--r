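sample_id	population	raw_bases	clean_bases	effective_rate	error_rate	q20	q30	gc_content
AB01	fast	48216007500	47152467900	97.79	0.03	96.21	92.24	42.89
AB02	fast	43047445800	42340444800	98.36	0.03	96.17	92.1	42.65
AB03	fast	47273694300	46714855800	98.82	0.03	95.76	91.36	42.55
AB04	fast	48416284200	47906212800	98.95	0.03	95.96	91.47	42.13
WS01	slow	49415626200	48784894800	98.72	0.03	95.69	91.23	41.97
WS02	slow	53074008900	52417962000	98.76	0.03	96.09	92.19	42.35
WS03	slow	45358642200	44789835900	98.75	0.03	95.87	91.47	41.97
WS04	slow	47681665800	47139254400	98.86	0.03	95.94	91.6	41.66
WS05	slow	50647742700	50012300700	98.75	0.03	95.86	91.47	41.84
WS06	slow	45072226800	44633740200	99.03	0.03	95.79	91.61	42.19
WS07	slow	34681049100	34040596500	98.15	0.05	92.2	84.65	43.07
WS08	slow	45212322600	44350535700	98.09	0.04	92.41	84.97	43.02
WS09	slow	44382563100	43593247800	98.22	0.04	92.47	85.07	43.23
WS10	slow	37244331900	36659027100	98.43	0.04	92.91	85.77	43.12
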