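chrom	length_bp
chr1	59600000
chr2	59800000
chr3	58900000
chr4	59700000
chr5	75700000
chr6	59900000
chr7	77300000
chr8	56200000
chr9	58200000
chr10	46600000
chr11	46700000
chr12	50700000
chr13	54100000
chr14	53700000
chr15	47600000
chr16	58800000
chr17	53900000
chr18	49900000
chr19	50600000
chr20	55400000
chr21	44500000
chr22	42300000
chr23	46400000
chr24	43900000
chr25	38500000
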