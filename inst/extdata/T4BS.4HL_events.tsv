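kind	chrom	start_mb	end_mb	partner	arm	copy_number_change
arm_replacement	4B	.	.	4H	L	.
interstitial_deletion	2D	573	622	.	.	.
terminal_loss	3B	724	851	.	.	.
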