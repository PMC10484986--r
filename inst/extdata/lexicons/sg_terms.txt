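# sex/gender terms: full words whole-word, truncated stems prefix-stem
sex	whole_word
gender	whole_word
woman	whole_word
women	whole_word
man	whole_word
men	whole_word
female	whole_word
females	whole_word
male	whole_word
males	whole_word
girl	whole_word
girls	whole_word
boy	whole_word
boys	whole_word
pregnan	prefix_stem
transg	prefix_stem
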