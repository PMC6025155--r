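C1000001|A0001|SCUI|IS_A|C1000009|A0016|SCUI||R0001||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000003|A0006|SCUI|IS_A|C1000009|A0016|SCUI||R0002||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000004|A0007|SCUI|IS_A|C1000009|A0016|SCUI||R0003||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000005|A0008|SCUI|IS_A|C1000009|A0016|SCUI||R0004||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000006|A0010|SCUI|IS_A|C1000009|A0016|SCUI||R0005||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000007|A0012|SCUI|IS_A|C1000009|A0016|SCUI||R0006||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000008|A0014|SCUI|IS_A|C1000009|A0016|SCUI||R0007||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000002|A0004|SCUI|IS_A|C1000010|A0018|SCUI||R0008||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000011|A0019|SCUI|IS_A|C1000010|A0018|SCUI||R0009||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000012|A0021|SCUI|IS_A|C1000010|A0018|SCUI||R0010||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000001|A0001|SCUI|may_treat|C1000002|A0004|SCUI||R0011||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000004|A0007|SCUI|may_treat|C1000012|A0021|SCUI||R0012||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000006|A0010|SCUI|may_treat|C1000011|A0019|SCUI||R0013||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000005|A0008|SCUI|associated_with|C1000012|A0021|SCUI||R0014||SNOMEDCT_US|SNOMEDCT_US|||N|256
C1000003|A0006|SCUI|associated_with|C1000002|A0004|SCUI||R0015||SNOMEDCT_US|SNOMEDCT_US|||N|256
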