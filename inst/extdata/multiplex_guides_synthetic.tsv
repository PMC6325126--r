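# Six-guide multiplex set: reconstruction of the commonly used target sites
# for these loci from the primary CRISPR literature.  The authoritative
# per-experiment sequences were published only as supplementary material and
# are not bundled; treat these as a synthetic stand-in with the correct
# names, lengths (HBB-28 is an 18-nt guide) and PAMs.  The pam column
# carries each target's concrete genomic PAM; all are NGG-compatible.
name	protospacer	pam
HEK293-2	GAACACAAAGCATAGACTGC	GGG
EMX1	GAGTCCGAGCAGAAGAAGAA	GGG
FANCF	GGAATCCCTTCTGCAGCACC	TGG
HBB-28	GACTTCTATGCCCAGCCC	TGG
RNF2	GTCATCTTAGTCATTACCTG	AGG
HBG	CTTGTCAAGGCTATTGGTCA	AGG
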