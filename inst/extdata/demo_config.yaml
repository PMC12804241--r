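letters: ["a", "b", "c", "e", "f", "g", "h", "i", "l", "m", "n", "p", "s", "t"]
phonemes: ["æ", "ɑɪ", "ɪ", "iː", "k", "t", "θ", "m", "n", "p", "l", "h", "f", "g", "dʒ", "tʃ", "s", "ʃ", "b"]
vowel_letters: ["a", "e", "i"]
vowel_phonemes: ["æ", "ɑɪ", "ɪ", "iː"]
syllabic_consonants: []
strip_symbols: ["ˈ", "ˌ"]
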