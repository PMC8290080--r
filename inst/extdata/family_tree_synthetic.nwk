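((Atypidae,Dipluridae),((Theridiidae,((Tetragnathidae,Nephilidae),Araneidae)),(Oecobiidae,(Zodariidae,(((Gnaphosidae,Viridasiidae),((Salticidae,Philodromidae),(Anyphaenidae,Eutichuridae))),(Sparassidae,((Amaurobiidae,Agelenidae),(Zoropsidae,((Thomisidae,Oxyopidae),((Ctenidae,Trechaleidae),(Pisauridae,Lycosidae)))))))))));
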