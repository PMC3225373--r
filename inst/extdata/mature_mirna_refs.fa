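>miR156/157 miR156/157
UUGACAGAAGAUAGAGAGCGC
>miR159 miR159
UUUGGAUUGAAGGGAGCUCUA
>miR160 miR160
UGCCUGGCUCCCUGUAUGCCA
>miR164 miR164
UGGAGAAGCAGGGCACGUGCA
>miR166 miR166
UCGGACCAGGCUUCAUUCCUC
>miR166* miR166*
GGAAUGUUGGCUGGCUCGAGGC
>miR167 miR167
UGAAGCUGCCAGCAUGAUC
>miR168 miR168
UCGCUUGGUGCAGGUCGGGAA
>miR168* miR168*
CCCGCCUUGCAUCAACUGAAU
>miR171 miR171
UGAUUGAGCCGUGCCAAUAUC
>miR172 miR172
AGAAUCUUGAUGAUGCUGCAU
>miR390 miR390
AGCUCAGGAGGGAUAGCGCC
>miR396 miR396
UUCCACAGCUUUCUUGAA
>miR396* miR396*
GUUCAAGAAAGCUGUGGGACA
>miR482-a miR482
UCUUACCAAUGCCUCCCAUCCC
>miR482-b miR482
UUUCCUAUUCCUCCCAUACCGA
>miR845 miR845
AGGCUUUGAUACCACUUG
>miR858 miR858
UUCGUUGUCUGUUCGACCUUA
>miR894 miR894
UGUUUCACGUCGGGUUCACCA
>miR1310 miR1310
GAGGCAUCGGGGGCGCAA
>miR2911 miR2911
GCCGGGGGACGGACUUGGA
>miR4342 miR4342
CUAAGGAUGUAGGGUGGU
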