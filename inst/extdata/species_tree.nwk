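(Nvectensis,(((Dmelanogaster,Celegans)Ecdysozoa,Lgigantea)Protostomia,((Spurpuratus,Skowalevskii)Ambulacraria,(Bfloridae,((Pmarinus,(Drerio,(Xtropicalis,(Ggallus,(Hsapiens,Mmusculus)Mammalia)Amniota)Tetrapoda)Gnathostomata)Vertebrata,(Odioica,(Hroretzi,(Cintestinalis,Csavignyi)Ciona)Ascidiacea)Tunicata)Olfactores)Chordata)Deuterostomia)Nephrozoa)Eumetazoa;
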