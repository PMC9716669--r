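group	n_replicates	raw_reads	clean_reads	hq_reads
35dpf	6	131089291	125467629	120504506
40dpf	6	137511710	131438793	125838273
45dpf_T	3	67892811	64566141	61911523
45dpf_O	3	66575176	63469904	60325179
50dpf_T	3	72436212	67841216	64953286
50dpf_O	3	69308994	65575560	62900148
55dpf_T	3	70153273	66537054	63844072
55dpf_O	3	68790439	66541194	63802264
60dpf_T	5	118404154	113674531	108186876
60dpf_O	5	115312123	108869947	103308251
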