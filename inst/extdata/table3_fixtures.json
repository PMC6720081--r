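[
  {
    "study_id": "example-1-fit-colorectal",
    "index_test": {
      "name": "faecal immunochemical testing",
      "result_scale": "continuous_with_cutoff",
      "cutoff": "positivity threshold of the FIT assay",
      "is_combination": false
    },
    "reference_test": {
      "name": "colonoscopy with histological evaluation",
      "result_scale": "binary",
      "is_combination": false
    },
    "has_reference_standard": true,
    "cross_tab_derivable": true,
    "individual_interval_days": 0,
    "interval_basis": "reported",
    "sampling_basis": "suspicion",
    "treatment_context": "unclear",
    "index_blinded_during_followup": "unclear",
    "sampling_mechanism": "consecutive",
    "comparative_design": false,
    "data_source": "kidney transplant recipients aged >= 50 years; colorectal cancer screening",
    "condition_progression": "slow"
  },
  {
    "study_id": "example-2-cognitive-alzheimer",
    "index_test": {
      "name": "brief cognitive test",
      "result_scale": "categorical_with_cutoff",
      "cutoff": "test-specific impairment threshold",
      "is_combination": false
    },
    "reference_test": {
      "name": "clinical diagnosis of Alzheimer's disease",
      "result_scale": "binary",
      "is_combination": false
    },
    "has_reference_standard": true,
    "cross_tab_derivable": true,
    "individual_interval_days": 0,
    "interval_basis": "reported",
    "sampling_basis": "outcome_status",
    "matching_ratio": 3,
    "treatment_context": "unclear",
    "index_blinded_during_followup": "unclear",
    "sampling_mechanism": "convenience",
    "comparative_design": false,
    "data_source": "memory clinic attendees; controls recruited from accompanying relatives",
    "condition_progression": "slow"
  },
  {
    "study_id": "example-3-fracture-model",
    "index_test": {
      "name": "prognostic model score for osteoporotic fracture",
      "result_scale": "continuous_with_cutoff",
      "cutoff": "dichotomised at pre-specified score cut-offs",
      "is_combination": true
    },
    "reference_test": {
      "name": "hip fracture occurrence",
      "result_scale": "binary",
      "is_combination": false
    },
    "has_reference_standard": true,
    "cross_tab_derivable": true,
    "individual_interval_days": 1825,
    "interval_basis": "reported",
    "sampling_basis": "suspicion",
    "treatment_context": "untreated_natural_course",
    "index_blinded_during_followup": "unclear",
    "sampling_mechanism": "consecutive",
    "comparative_design": false,
    "data_source": "payer provider health organisation, all patients aged 50-90",
    "condition_progression": "unclear"
  },
  {
    "study_id": "example-4-psa-prostate",
    "index_test": {
      "name": "prostate-specific antigen from blood draw",
      "result_scale": "continuous_with_cutoff",
      "cutoff": "categorised PSA levels",
      "is_combination": false
    },
    "reference_test": {
      "name": "prostate cancer diagnosed by biopsy",
      "result_scale": "binary",
      "is_combination": false
    },
    "has_reference_standard": true,
    "cross_tab_derivable": true,
    "individual_interval_days": 2591.5,
    "interval_basis": "reported",
    "sampling_basis": "outcome_status",
    "treatment_context": "untreated_natural_course",
    "index_blinded_during_followup": "unclear",
    "sampling_mechanism": "convenience",
    "comparative_design": false,
    "data_source": "nested in a population-based cohort; 540 cases and 1034 controls matched for age and date of blood draw",
    "condition_progression": "unclear"
  }
]
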