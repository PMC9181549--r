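code	direction	sequence
ANG RNase+	forward	ATGGGACTTCGWTATTCTAGTG
ANG 1-	reverse	TTTGAGAGCGGGTCAGTCCAA
ANG 3-	reverse	CCATTCAATAACATCATCATCT
ANG 44-	reverse	TTATTTACTTATGTTATTTACCA
ANG 44+	forward	ATTGGTAAATAACATAAGTAAAT
ANG 4-	reverse	CACAAGCTTGTATACCCCAAG
ANG 5+	forward	TTCAAGAATCACACCCTCTA
ANG 55+	forward	TCATAACCTAGCCAAGACCT
ANG 55-	reverse	AGGTCTTGGCTAGGTTATGA
ANG 6+	forward	AACAAACGCGACAAACTAAAAC
ANG gag-	reverse	CAATTCTCAAGTTTCGATACCA
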