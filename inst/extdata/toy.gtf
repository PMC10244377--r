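##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-30
chrT	rtracklayer	exon	1000	1102	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	gene	1000	13904	.	-	.	gene_id "gene001"; gene_biotype "noncoding"
chrT	rtracklayer	transcript	1000	13904	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	3273	3563	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	6350	6601	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	11679	11810	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	13768	13904	.	-	.	gene_id "gene001"; transcript_id "gene001.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	17570	17868	.	-	.	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	gene	17570	23494	.	-	.	gene_id "gene002"; gene_biotype "protein_coding"
chrT	rtracklayer	transcript	17570	23494	.	-	.	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	17620	17868	.	-	0	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	19160	19414	.	-	.	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	19160	19414	.	-	0	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	22649	22842	.	-	.	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	22649	22842	.	-	0	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	23349	23444	.	-	0	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	23349	23494	.	-	.	gene_id "gene002"; transcript_id "gene002.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	25529	25827	.	+	.	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	gene	25529	34098	.	+	.	gene_id "gene003"; gene_biotype "protein_coding"
chrT	rtracklayer	transcript	25529	34098	.	+	.	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	25579	25827	.	+	0	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	28176	28309	.	+	.	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	28176	28309	.	+	0	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	30960	31139	.	+	.	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	30960	31139	.	+	0	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	33952	34048	.	+	0	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	33952	34098	.	+	.	gene_id "gene003"; transcript_id "gene003.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	40611	40724	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	gene	40611	75221	.	+	.	gene_id "gene004"; gene_biotype "protein_coding"
chrT	rtracklayer	transcript	40611	75221	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	40661	40724	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	45373	45577	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	45373	45577	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	46769	46955	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	46769	46955	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	48094	48316	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	48094	48316	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	55285	55416	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	55285	55416	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	62986	63206	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	62986	63206	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	68789	69051	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	68789	69051	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	74929	75171	.	+	0	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	74929	75221	.	+	.	gene_id "gene004"; transcript_id "gene004.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	82325	82504	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	gene	82325	96915	.	-	.	gene_id "gene005"; gene_biotype "protein_coding"
chrT	rtracklayer	transcript	82325	96915	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	82375	82504	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	89936	90230	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	89936	90230	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	91894	92083	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	91894	92083	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	93073	93296	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	93073	93296	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	95903	96068	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	95903	96068	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	CDS	96706	96865	.	-	0	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	96706	96915	.	-	.	gene_id "gene005"; transcript_id "gene005.t1"; gene_biotype "protein_coding"
chrT	rtracklayer	exon	101154	101349	.	-	.	gene_id "gene006"; transcript_id "gene006.t1"; gene_biotype "noncoding"
chrT	rtracklayer	gene	101154	110500	.	-	.	gene_id "gene006"; gene_biotype "noncoding"
chrT	rtracklayer	transcript	101154	110500	.	-	.	gene_id "gene006"; transcript_id "gene006.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	104632	104783	.	-	.	gene_id "gene006"; transcript_id "gene006.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	107134	107402	.	-	.	gene_id "gene006"; transcript_id "gene006.t1"; gene_biotype "noncoding"
chrT	rtracklayer	exon	110249	110500	.	-	.	gene_id "gene006"; transcript_id "gene006.t1"; gene_biotype "noncoding"
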