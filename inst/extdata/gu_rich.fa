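>miR-574-5p
UGAGUGUGUGUGUGUGAGUGUGU
>miR-941
CACCCGGCUGUGUGCACAUGUGC
>miR-3149
UUUGUAUGGAUAUGUGUGUGUAU
>miR-1238-5p
GUGAGUGGGAGCCCCAGUGUGUG
>miR-545-3p
UCAGCAAACAUUUAUUGUGUGC
>miR-2278
GAGAGCAGUGUGUGUUGCCUGG
>miR-3148
UGGAAAAAACUGGUGUGUGCUU
>let-7b-5p
UGAGGUAGUAGGUUGUGUGGUU
>miR-493-3p
UGAAGGUCUACUGUGUGCCAGG
>miR-1180
UUUCCGGCUCGCGUGGGUGUGU
>miR-539-5p
GGAGAAAUUAUCCUUGGUGUGU
>miR-32-3p
CAAUUUAGUGUGUGUGAUAUUU
>miR-206
UGGAAUGUAAGGAAGUGUGUGG
>miR-1299
UUCUGGAAUUCUGUGUGAGGGA
>miR-3911
UGUGUGGAUCCUGGAGGAGGCA
>miR-297
AUGUAUGUGUGCAUGUGCAUG
>miR-610
UGAGCUAAAUGUGUGCUGGGA
>miR-1228-5p
GUGGGCGGGGGCAGGUGUGUG
>miR-595
GAAGUGUGCCGUGGUGUGUCU
>miR-4455
AGGGUGUGUGUGUUUUU
>miR-3650
AGGUGUGUCUGUAGAGUCC
>miR-147a
GUGUGUGGAAAUGCUUCUGC
>miR-660-3p
ACCUCCUGUGUGCAUGGAUUA
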