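>protA1
MAAAGGGKEEEFFFRHHHIIIK
>protA1frag
EEEFFFRHHHIIIK
>protA2
MAAAGGGKEEEYFFRHHHIIIK
>protB1
MCCCDDDKLLLMMMRNNNQQQK
>protB2
MCCCDDDKLLLWMMRNNNQQWK
>protC1
MWWWYYYKVVVTTTRSSSEEEK
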