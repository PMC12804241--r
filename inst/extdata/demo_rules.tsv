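grapheme	phoneme	position	pre	post
ch	tʃ	any		
sh	ʃ	any		
th	θ	any		
ea	iː	any		
ee	iː	any		
ll	l	any		
e		final		
a	æ	any		
b	b	any		
c	k	any		
f	f	any		
g	g	any		
h	h	any		
i	ɪ	any		
l	l	any		
m	m	any		
n	n	any		
p	p	any		
s	s	any		
t	t	any		
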