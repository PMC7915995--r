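{
  "dimensions": [
    {"id": "D1", "label": "Comorbidity"},
    {"id": "D2", "label": "Laboratory Values"},
    {"id": "D3", "label": "Comprehensive Geriatric Assessments"}
  ],
  "criteria": [
    {"id": "C11", "label": "Diabetes", "dimension": "D1"},
    {"id": "C12", "label": "Hypertension", "dimension": "D1"},
    {"id": "C13", "label": "Depression", "dimension": "D1"},
    {"id": "C14", "label": "Malignancy", "dimension": "D1"},
    {"id": "C15", "label": "Hepatitis B/C", "dimension": "D1"},
    {"id": "C21", "label": "Creatinine", "dimension": "D2"},
    {"id": "C22", "label": "Estimated glomerular filtration rate", "dimension": "D2"},
    {"id": "C23", "label": "Hemoglobin", "dimension": "D2"},
    {"id": "C24", "label": "Albumin", "dimension": "D2"},
    {"id": "C25", "label": "Na", "dimension": "D2"},
    {"id": "C31", "label": "Activities of daily living", "dimension": "D3"},
    {"id": "C32", "label": "Mid-arm circumference", "dimension": "D3"},
    {"id": "C33", "label": "Frailty", "dimension": "D3"},
    {"id": "C34", "label": "Nutritional assessment", "dimension": "D3"}
  ]
}
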