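# HPV strings (MeSH-derived); phrases are substrings, bare "hpv" both modes
human papillomavirus	substring
hpv human papillomavirus	substring
alphapapillomaviruses	substring
hpv human papillomaviruses	substring
papillomavirus, human	substring
human papillomaviruses, hpv	substring
papillomaviruses, human	substring
human papillomaviruses	substring
hpv	whole_word
hpv	substring
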