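C1000001|ENG|P|L0001|PF|S0001|Y|A0001|||S001|SNOMEDCT_US|PT|387458008|Aspirin|0|N|256
C1000001|ENG|S|L0002|PF|S0002|Y|A0002|||S001|SNOMEDCT_US|SY|387458008|Acetylsalicylic acid|0|N|256
C1000001|ENG|S|L0003|PF|S0003|Y|A0003|||R001|RXNORM|SY|1191|ASA|0|N|256
C1000002|ENG|P|L0004|PF|S0004|Y|A0004|||S002|SNOMEDCT_US|PT|25064002|Headache|0|N|256
C1000002|ENG|S|L0005|PF|S0005|Y|A0005|||S002|SNOMEDCT_US|SY|25064002|Cephalalgia|0|N|256
C1000003|ENG|P|L0006|PF|S0006|Y|A0006|||S003|SNOMEDCT_US|PT|387506000|Atenolol|0|N|256
C1000004|ENG|P|L0007|PF|S0007|Y|A0007|||S004|SNOMEDCT_US|PT|386851000|Trazodone|0|N|256
C1000005|ENG|P|L0008|PF|S0008|Y|A0008|||S005|SNOMEDCT_US|PT|387564004|Bupropion|0|N|256
C1000005|ENG|S|L0009|PF|S0009|Y|A0009|||R002|RXNORM|SY|42347|Wellbutrin|0|N|256
C1000006|ENG|P|L0010|PF|S0010|Y|A0010|||S006|SNOMEDCT_US|PT|386876001|Valsartan|0|N|256
C1000006|ENG|S|L0011|PF|S0011|Y|A0011|||R003|RXNORM|SY|69749|Diovan|0|N|256
C1000007|ENG|P|L0012|PF|S0012|Y|A0012|||S007|SNOMEDCT_US|PT|108696005|Tazarotene|0|N|256
C1000007|ENG|S|L0013|PF|S0013|Y|A0013|||R004|RXNORM|SY|37801|Tazorac|0|N|256
C1000008|ENG|P|L0014|PF|S0014|Y|A0014|||S008|SNOMEDCT_US|PT|387305005|Tretinoin|0|N|256
C1000008|ENG|S|L0015|PF|S0015|Y|A0015|||R005|RXNORM|SY|10778|Retin-A|0|N|256
C1000009|ENG|P|L0016|PF|S0016|Y|A0016|||S009|SNOMEDCT_US|PT|410942007|Drug|0|N|256
C1000009|ENG|S|L0017|PF|S0017|Y|A0017|||S009|SNOMEDCT_US|SY|410942007|Medication|0|N|256
C1000010|ENG|P|L0018|PF|S0018|Y|A0018|||S010|SNOMEDCT_US|PT|64572001|Disease|0|N|256
C1000011|ENG|P|L0019|PF|S0019|Y|A0019|||S011|SNOMEDCT_US|PT|197359004|Cirrhosis of liver|0|N|256
C1000011|ENG|S|L0020|PF|S0020|Y|A0020|||S011|SNOMEDCT_US|SY|197359004|Hepatic cirrhosis|0|N|256
C1000012|ENG|P|L0021|PF|S0021|Y|A0021|||S012|SNOMEDCT_US|PT|271681002|Insomnia|0|N|256
C1000012|ENG|S|L0022|PF|S0022|Y|A0022|||S012|SNOMEDCT_US|SY|271681002|Sleeplessness|0|N|256
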