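orthography	phonology	frequency
cat	kæt	41
that	θæt	389
mint	mɪnt	7
pint	pɑɪnt	4
mill	mɪl	13
hill	hɪl	22
fill	fɪl	29
gift	gɪft	16
gist	dʒɪst	2
chat	tʃæt	9
bite	bɑɪt	11
tip	tɪp	14
seat	siːt	27
sheet	ʃiːt	18
hint	hɪnt	8
mist	mɪst	6
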