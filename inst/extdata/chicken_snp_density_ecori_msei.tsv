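chrom	length_bp	snps
chr1	195276750	27690
chr2	148809762	20915
chr3	110447801	17220
chr4	90216835	12425
chr5	59580361	7751
chr6	34951654	5490
chr7	36245040	4994
chr8	28767244	4267
chr9	23441680	3997
chr10	19911089	2410
chr11	19401079	2666
chr12	19897011	2863
chr13	17760035	2246
chr14	15161805	1990
chr15	12656803	1420
chr16	535270	74
chr17	10454150	1250
chr18	11219875	1043
chr19	9983394	1345
chr20	14302601	1927
chr21	6802778	856
chr22	4081097	402
chr23	5723239	865
chr24	6323281	762
chr25	2191139	176
chr26	5329985	553
chr27	5209285	649
chr28	4742627	490
chrZ	82363669	5451
chrW	1248174	104
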