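# Default concept sets for the SLE phenotype algorithms.
# Matching is exact on (vocabulary, code); supply complete production code
# lists through your own file with the same schema if needed.
concept_sets:
  - name: sle_diagnosis
    role: sle_diagnosis
    codes:
      - {vocabulary: SNOMED,   code: "257628",  label: "Systemic lupus erythematosus"}
      - {vocabulary: ICD10CM,  code: "M32.9",   label: "Systemic lupus erythematosus, unspecified"}
      - {vocabulary: ICD9CM,   code: "710.0",   label: "Systemic lupus erythematosus"}
  - name: sle_signs_symptoms
    role: sle_sign_symptom
    codes:
      - {vocabulary: ICD10CM,  code: "R53.81",  label: "Malaise"}
      - {vocabulary: ICD10CM,  code: "R53.83",  label: "Fatigue"}
      - {vocabulary: ICD10CM,  code: "M25.50",  label: "Joint pain, unspecified"}
      - {vocabulary: ICD9CM,   code: "719.40",  label: "Joint pain, unspecified site"}
      - {vocabulary: ICD10CM,  code: "M54.5",   label: "Low back pain"}
      - {vocabulary: ICD10CM,  code: "D64.9",   label: "Anemia, unspecified"}
  - name: sle_treatment_drugs
    role: sle_treatment_drug
    codes:
      - {vocabulary: RxNorm,   code: "8640",    label: "Prednisone"}
      - {vocabulary: RxNorm,   code: "6902",    label: "Methylprednisolone"}
      - {vocabulary: RxNorm,   code: "5521",    label: "Hydroxychloroquine"}
  - name: antimalarials
    role: antimalarial
    codes:
      - {vocabulary: RxNorm,   code: "5521",    label: "Hydroxychloroquine"}
      - {vocabulary: RxNorm,   code: "2393",    label: "Chloroquine"}
  - name: barnado_exclusions
    role: exclusion_dx
    codes:
      - {vocabulary: ICD9CM,   code: "710.3",   label: "Dermatomyositis"}
      - {vocabulary: ICD9CM,   code: "710.1",   label: "Systemic sclerosis"}
  - name: rheumatoid_arthritis
    role: comorbidity
    codes:
      - {vocabulary: ICD10CM,  code: "M06.9",   label: "Rheumatoid arthritis, unspecified"}
  - name: renal_impairment
    role: comorbidity
    codes:
      - {vocabulary: ICD10CM,  code: "N28.9",   label: "Disorder of kidney and ureter, unspecified"}
  - name: heart_disease
    role: comorbidity
    codes:
      - {vocabulary: ICD10CM,  code: "I51.9",   label: "Heart disease, unspecified"}
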