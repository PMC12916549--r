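name	subgenome	length_mb	centromere_mb	group
1A	wheat	598	213	1
1B	wheat	700	240	1
1D	wheat	498	168	1
2A	wheat	787	326	2
2B	wheat	812	348	2
2D	wheat	665	268	2
3A	wheat	754	317	3
3B	wheat	851	354	3
3D	wheat	631	241	3
4A	wheat	754	265	4
4B	wheat	673	317	4
4D	wheat	525	185	4
5A	wheat	713	253	5
5B	wheat	714	200	5
5D	wheat	566	186	5
6A	wheat	622	286	6
6B	wheat	731	345	6
6D	wheat	495	214	6
7A	wheat	744	363	7
7B	wheat	764	310	7
7D	wheat	642	339	7
1H	barley	522	205	1
2H	barley	665	305	2
3H	barley	622	271	3
4H	barley	647	312	4
5H	barley	597	217	5
6H	barley	560	253	6
7H	barley	657	329	7
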