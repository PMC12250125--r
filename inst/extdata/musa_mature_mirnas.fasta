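>miR169j-5p homolog=ata-miR169j-5p loc=5p strand=-
UAGCCAAGGAUGAUUUGCCUGUG
>miR156f homolog=gma-miR156f loc=5p strand=-
UUGACAGAAGAGAGAGAGCACA
>miR156a-3p homolog=vca-miR156a-3p loc=3p strand=+
UGCUCACUUCUCUUUCUGUCAG
>miR482a homolog=fve-miR482a loc=3p strand=+
UCUUUCCAAUUCCUCCCAUGCC
>miR528-5p homolog=osa-miR528-5p loc=5p strand=+
UGGAAGGGGCAUGCAGAGGAG
>miR397a homolog=bna-miR397a loc=5p strand=+
UCAUUGAGUGCAGCGUUGAUGU
>miR399a homolog=osa-miR399a loc=3p strand=+
UGCCAAAGGAGAAUUGCCCUG
>miR160h homolog=ptc-miR160h loc=5p strand=-
UGCCUGGCUCCCUGCAUGCCA
>miR530-5p homolog=osa-miR530-5p loc=5p strand=+
UGCAUUUGCACCUGCACCUA
>miR397-5p homolog=stu-miR397-5p loc=5p strand=+
AUUGAGUGCAGCGUUGAUGAC
>miR169a homolog=pab-miR169a loc=5p strand=-
UCAGCCAAGAAUGACUUGCCC
>miR160 homolog=ctr-miR166 loc=5p strand=+
UCGGACCAGGCUUCAUUCCCCC
>miR156j homolog=cme-miR156j loc=5p strand=+
GUUGACAGAAGAGAGUGAGCAC
>miR398a-3p homolog=ath-miR398a-3p loc=3p strand=-
UGUGUUCUCAGGUCACCCCUU
>miR166e-3p homolog=bdi-miR166e-3p loc=3p strand=+
CUCGGACCAGGCUUCAUUCCC
>miR166h-3p homolog=gma-miR166h-3p loc=3p strand=+
UCUCGGACCAGGCUUCAUUCC
>miR172i homolog=ptc-miR172i loc=3p strand=+
AGAAUCCUGAUGAUGCUGCAA
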