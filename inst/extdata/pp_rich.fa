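>hsa-miR-4290
UGCCCUCCUUUCUUCCCUC
>hsa-miR-1281
UCGCCUCCUCCUCUCCC
>hsa-miR-4716-5p
UCCAUGUUUCCUUCCCCCUUCU
>hsa-miR-483-3p
UCACUCCUCUCCUCCCGUCUU
>hsa-miR-877-3p
UCCUCUUCUCCCUCCUCCCAG
>hsa-miR-6124
GGGAAAAGGAAGGGGGAGGA
>hsa-miR-4271
GGGGGAAGAAAAGGUGGGG
>hsa-miR-483-5p
AAGACGGGAGGAAAGAAGGGAG
>hsa-miR-4644
UGGAGAGAGAAAAGAGACAGAAG
>hsa-miR-4716-3p
AAGGGGGAAGGAAACAUGGAGA
>hsa-miR-1234-5p
GGGGGGGGGGGGGGGGGGCCG
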