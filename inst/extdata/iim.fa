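>miR-3682-5p
CUACUUCUACCUGUGUUAUCAU
>miR-2278
GAGAGCAGUGUGUGUUGCCUGG
>miR-1238-5p
GUGAGUGGGAGCCCCAGUGUGUG
>miR-3149
UUGUAUGGAUAUGUGUGUGUAU
>let-7b-5p
UGAGGUAGUAGGUUGUGUGGUU
>miR-4455
AGGGUGUGUGUGUUUUU
>miR-4717-5p
UAGGCCACAGCCACCCAUGUGU
>miR-573
CUGAAGUGAUGUGUAACUGAUCAG
>miR-660-3p
ACCUCCUGUGUGCAUGGAUUA
>miR-378a-5p
CUCCUGACUCCAGGUCCUGUGU
>miR-599
GUUGUGUCAGUUUAUCAAAC
>miR-1226-3p
UCACCAGCCCUGUGUUCCCUAG
>miR-1270
CUGGAGAUAUGGAAGAGCUGUGU
>miR-610
UGAGCUAAAUGUGUGCUGGGA
>miR-3911
UGUGUGGAUCCUGGAGGAGGCA
>miR-3650
AGGUGUGUCUGUAGAGUCC
>miR-4789-5p
GUAUACACCUGAUAUGUGUAUG
>miR-330-5p
UCUCUGGGCCUGUGUCUUAGGC
>miR-941
CACCCGGCUGUGUGCACAUGUGC
>miR-597
UGUGUCACUCGAUGACCACUGU
>miR-5580-5p
UGCUGGCUCAUUUCAUAUGUGU
>miR-4700-5p
UCUGGGGAUGAGGACAGUGUGU
>miR-892a
CACUGUGUCCUUUCUGCGUAG
>miR-206
UGGAAUGUAAGGAAGUGUGUGG
>miR-595
GAAGUGUGCCGUGGUGUGUC
>miR-539-5p
GGAGAAAUUAUCCUUGGUGUGU
>miR-1180-3p
UUUCCGGCUCGCGUGGGUGUGU
>miR-450a-5p
UUUUGCGAUGUGUUCCUAAUAU
>miR-493-3p
UGAAGGUCUACUGUGUGCCAGG
>miR-4669
UGUGUCCGGGAAGUGGAGGAGG
>miR-4753-3p
UUCUCUUUCUUUAGCCUUGUGU
>miR-624-5p
UAGUACCAGUACCUUGUGUUCA
>miR-3657
UGUGUCCCAUUAUUGGUGAUU
>miR-3148
UGGAAAAAACUGGUGUGUGCUU
>miR-3177-5p
UGUGUACACACGUGCCAGGCGCU
>miR-581
UCUUGUGUUCUCUAGAUCAGU
>miR-642b-5p
GGUUCCCUCUCCAAAUGUGUCU
>miR-147a
GUGUGUGGAAAUGCUUCUGC
>miR-592
UUGUGUCAAUAUGCGAUGAUGU
>miR-545-3p
UCAGCAAACAUUUAUUGUGUGC
>miR-1228-5p
GUGGGCGGGGGCAGGUGUGUG
>iR-642a-5p
GUCCCUCUCCAAAUGUGUCUUG
>miR-3152-3p
UGUGUUAGAAUAGGGGCAAUAA
>miR-32-3p
CAAUUUAGUGUGUGUGAUAUUU
>miR-1299
UUCUGGAAUUCUGUGUGAGGGA
>miR-297
AUGUAUGUGUGCAUGUGCAUG
>miR-187-3p
UCGUGUCUUGUGUUGCAGCCGG
>miR-5010-3p
UUUUGUGUCUCCCAUUCCCCAG
>miR-574-5p
UGAGUGUGUGUGUGUGAGUGUGU
>miR-649
AAACCUGUGUUGUUCAAGAGUC
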