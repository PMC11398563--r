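file	md5
called_in_k4me1.bed	05b7ea034c153e42811f3b9b4274ec0d
called_in_k4me3.bed	5f1152715fec553c127294731107fbce
counts.tsv	1e986ec5c54789b7c823558ae7e86a2e
cycles.txt	7382ca64e5594e8154fb1defed22f7e2
differential.tsv	a25b31896d58caf127dcad5d600e7d13
ecdna_matrix_treated.tsv	c9e45ebc0ad7d3bc87a2b0ac9642fe79
ecdna_matrix_treated_bins.tsv	eca22660f9b35afaaa94a6847c47d62e
ecdna_matrix_vehicle.tsv	f537f0996bf182e12e8a177c89ceeda5
ecdna_matrix_vehicle_bins.tsv	33d5ab7d4b99aa371e0c85aa9b490764
hic_bins.tsv	da09694458bf7c188d296cdf2f785be2
hic_comparison_strata.tsv	89879701bae07bfb7c6217b6c398b97d
hic_vehicle.tsv	7937ef6fe96c31fb9e4d521c0595c730
k27ac.bed	d09169d69c328b3687ce2bd88155de60
k4me1.bed	fc9ea899c919d7b9b14aa57debcd7f2b
k4me3.bed	7a5fa1931a9b04dfdda49b908826526d
manifest.json	f39b2a0aff07359175a116d80524491a
samples.tsv	af9200eeb281e6c01a16fe2f7806931e
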