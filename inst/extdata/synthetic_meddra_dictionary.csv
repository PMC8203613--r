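# Synthetic MedDRA-like dictionary bundled with pvsignal.
# Term spellings follow field conventions but the mapping is a synthetic
# fixture for testing and simulation; it is NOT an extract of the licensed
# MedDRA dictionary.
[PT_SOC]
Hepatocellular injury,Hepatobiliary disorders
Cholestasis,Hepatobiliary disorders
Hyperbilirubinaemia,Hepatobiliary disorders
Jaundice,Hepatobiliary disorders
Hepatic enzyme increased,Hepatobiliary disorders
Acute kidney injury,Renal and urinary disorders
Renal impairment,Renal and urinary disorders
Proteinuria,Renal and urinary disorders
Renal tubular necrosis,Renal and urinary disorders
Glomerular filtration rate decreased,Renal and urinary disorders
Hypertriglyceridaemia,Metabolism and nutrition disorders
Hypercholesterolaemia,Metabolism and nutrition disorders
Hypokalaemia,Metabolism and nutrition disorders
Hyperglycaemia,Metabolism and nutrition disorders
Lipodystrophy acquired,Metabolism and nutrition disorders
Adrenal insufficiency,Endocrine disorders
Adrenal suppression,Endocrine disorders
Hypothyroidism,Endocrine disorders
Hyperthyroidism,Endocrine disorders
Cushingoid,Endocrine disorders
Diplopia,Eye disorders
Eyelid ptosis,Eye disorders
Progressive external ophthalmoplegia,Eye disorders
Vision blurred,Eye disorders
Eye pain,Eye disorders
Myocardial infarction,Cardiac disorders
Atrial fibrillation,Cardiac disorders
Cardiac failure,Cardiac disorders
Tachycardia,Cardiac disorders
Palpitations,Cardiac disorders
Diarrhoea,Gastrointestinal disorders
Nausea,Gastrointestinal disorders
Vomiting,Gastrointestinal disorders
Pancreatitis acute,Gastrointestinal disorders
Oesophageal candidiasis,Gastrointestinal disorders
Abortion spontaneous,"Pregnancy, puerperium and perinatal conditions"
Foetal growth restriction,"Pregnancy, puerperium and perinatal conditions"
Premature baby,"Pregnancy, puerperium and perinatal conditions"
Stillbirth,"Pregnancy, puerperium and perinatal conditions"
Premature rupture of membranes,"Pregnancy, puerperium and perinatal conditions"
[SMQ_PT]
Cholestasis and jaundice of hepatic origin,Cholestasis
Cholestasis and jaundice of hepatic origin,Jaundice
Cholestasis and jaundice of hepatic origin,Hyperbilirubinaemia
Acute pancreatitis,Pancreatitis acute
Hyperglycaemia/new onset diabetes mellitus,Hyperglycaemia
Acute renal failure,Acute kidney injury
Acute renal failure,Renal impairment
Acute renal failure,Renal tubular necrosis
Acute renal failure,Glomerular filtration rate decreased
"Pregnancy, labour and delivery complications and risk factors",Abortion spontaneous
"Pregnancy, labour and delivery complications and risk factors",Foetal growth restriction
"Pregnancy, labour and delivery complications and risk factors",Premature baby
"Pregnancy, labour and delivery complications and risk factors",Stillbirth
"Pregnancy, labour and delivery complications and risk factors",Premature rupture of membranes
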