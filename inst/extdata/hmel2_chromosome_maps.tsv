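chrom	length_bp	melpomene_cM	cydno_cM	hybrid_cM
chr1	17206585	54.6	54.5	56.2
chr2	9045316	50.7	47.5	44.4
chr3	10541528	53.7	50.2	49.9
chr4	9662098	48.1	50.5	46.9
chr5	9908586	51.0	50.2	48.7
chr6	14054175	47.8	54.5	49.9
chr7	14308859	53.7	52.2	50.2
chr8	9320449	49.3	49.8	49.6
chr9	8708747	46.3	50.8	52.3
chr10	17965481	56.7	55.9	53.8
chr11	11759272	52.5	49.8	51.4
chr12	16327298	51.0	52.9	52.9
chr13	18127314	55.8	54.2	56.8
chr14	9174305	50.2	44.4	55.3
chr15	10235750	49.0	50.8	49.3
chr16	10083215	47.5	50.8	52.0
chr17	14773299	58.2	49.2	48.3
chr18	16803890	53.1	48.8	52.9
chr19	16399344	51.0	53.9	54.1
chr20	14871695	51.3	54.9	51.7
chr21	13359691	49.6	48.1	51.1
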