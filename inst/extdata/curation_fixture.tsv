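sequence_id	genome_id	category	detection_tag	circular	length_bp	prophage	hallmark_count	terL_count	parA	parB	label	has_microbial_genes
VALID_01	HOST_001	1	hallmark	0	35000	1	2	1	0	0		TRUE
VALID_02	HOST_001	2	refseq	0	22000	1	1	1	0	0		TRUE
VALID_03	HOST_002	1	hallmark	1	41000	0	2	1	1	1		FALSE
VALID_04	HOST_002	2	refseq	0	18000	0	1	1	0	0		FALSE
VALID_05	HOST_003	1	noncaudo	1	6100	0	1	0	0	0		FALSE
VALID_06	HOST_003	2	noncaudo	0	6000	0	1	0	0	0		FALSE
VALID_07	HOST_004	1	noncaudo	0	5200	0	1	0	0	0		FALSE
VALID_08	HOST_004	1	hallmark	1	3200	0	1	0	0	0		FALSE
VALID_09	HOST_005	2	vdb	0	10500	0	1	0	0	0		FALSE
VALID_10	HOST_005	1	refseq	1	52000	0	2	1	1	1	plasmid extrachromosomal assembly	FALSE
DECOY_PHIX_1	HOST_001	1	refseq	1	5386	0	1	0	0	0	Enterobacteria phage PhiX174	FALSE
DECOY_PHIX_2	HOST_002	1	refseq	1	5386	0	1	0	0	0	Enterobacteria phage phiX174 control	FALSE
DECOY_CAT3_1	HOST_001	3	refseq	0	25000	0	1	0	0	0		FALSE
DECOY_CAT3_2	HOST_002	3	vdb	0	14000	1	1	0	0	0		TRUE
DECOY_CAT3_3	HOST_003	3	hallmark	1	33000	0	1	0	0	0		FALSE
DECOY_PRO_1	HOST_001	2	refseq	0	24000	1	0	0	0	0		TRUE
DECOY_PRO_2	HOST_002	2	vdb	0	15500	1	0	0	0	0		TRUE
DECOY_PRO_3	HOST_003	1	refseq	0	30500	1	0	0	0	0		TRUE
DECOY_LIN_1	HOST_004	1	hallmark	0	9800	0	1	0	0	0		FALSE
DECOY_LIN_2	HOST_005	2	refseq	0	7400	0	1	1	0	0		FALSE
DECOY_LIN_3	HOST_006	1	vdb	0	4200	0	1	0	0	0		FALSE
DECOY_NC5_1	HOST_004	1	noncaudo	0	4900	0	1	0	0	0		FALSE
DECOY_NC5_2	HOST_005	2	noncaudo	0	3100	0	1	0	0	0		FALSE
DECOY_CIRC_1	HOST_006	1	hallmark	1	2900	0	1	0	0	0		FALSE
DECOY_CIRC_2	HOST_006	1	refseq	1	1500	0	1	0	0	0		FALSE
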