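diabetes:
- diabet
- diabetes
- diabetic
- diabeetus
- diabetes mellitus
- hypertension
- obesity
- insulin
kidney_failure:
- kidney
- renal
- nephritis
- dialysis
bronchitis:
- bronchitis
- emphysema
- copd
- chronic obstructive pulmonary
- respiratory
myocardial_infarction:
- myocardial
- infarct
- angina
- ischemic heart
- coronary
tumor:
- cancer
- tumor
- tumour
- neoplasm
- leukemia
- lymphoma
- carcinoma
- metastatic
liver_disease:
- liver
- cirrhosis
- hepatitis
- hepatic
stroke:
- stroke
- cerebrovascular
- cerebral ischemia
- hemiplegia
heart_disease:
- heart failure
- valvular
- cardiomyopathy
- heart disease
- atrial fibrillation
asthma:
- asthma
- asthmatic
- wheezing
arthritis:
- arthritis
- arthrosis
- osteoarthritis
- rheumatoid
- gout
- lupus
- fibromyalgia
- musculoskeletal
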