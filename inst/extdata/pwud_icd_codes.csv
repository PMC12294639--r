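# ICD-9/ICD-10 diagnosis codes qualifying an encounter for the PWUD cohort.
# ICD10 rows are code-family prefixes matched after dot-stripping (F11 covers
# F11.x; T402 covers T40.2X1A); ICD9 rows are exact dot-stripped codes.
# The hepatitis C ICD-9 code sometimes typeset as "0.70.41" is the standard
# 070.41 (see its siblings 070.44-070.71).
system,code,description
ICD10,F11,Opioid-related disorders
ICD10,F14,Cocaine-related disorder
ICD10,F15,Other stimulant-related disorders
ICD10,T400,Poisoning by opium
ICD10,T401,Poisoning by heroin
ICD10,T402,Poisoning by other opioids
ICD10,T403,Poisoning by methadone
ICD10,T404,Poisoning by synthetic narcotics
ICD10,T405,Poisoning by cocaine
ICD10,T406,Poisoning by unspecified narcotics
ICD10,T436,Poisoning by psychostimulants
ICD10,B18.2,Chronic viral hepatitis C
ICD9,070.41,Acute hepatitis C with hepatic coma
ICD9,070.44,Chronic hepatitis C with hepatic coma
ICD9,070.51,Acute hepatitis C without mention of hepatic coma
ICD9,070.54,Chronic hepatitis C without mention of hepatic coma
ICD9,070.70,Unspecified viral hepatitis C without hepatic coma
ICD9,070.71,Unspecified viral hepatitis C with hepatic coma
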