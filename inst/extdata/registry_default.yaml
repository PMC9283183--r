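# Default code registry shipped with fracturepathways.
#
# All codes below are SYNTHETIC placeholders (e.g. "FXDX_HIP_1"), not licensed
# ICD-9/10-CM, CPT, HCPCS or NDC content. The registry is fully data-driven:
# users with access to real code lists supply their own file with the same
# structure. The synthetic vocabulary is what the packaged claims generator
# emits, so the shipped registry and generator are mutually consistent.

hierarchy:
  - hip
  - femur
  - pelvis
  - vertebral
  - humerus
  - radius_ulna
  - tibia_fibula
  - ankle
  - clavicle

fracture_dx:
  hip: [FXDX_HIP_1, FXDX_HIP_2]
  femur: [FXDX_FEM_1, FXDX_FEM_2]
  pelvis: [FXDX_PEL_1, FXDX_PEL_2]
  vertebral: [FXDX_VER_1, FXDX_VER_2]
  humerus: [FXDX_HUM_1, FXDX_HUM_2]
  radius_ulna: [FXDX_RAD_1, FXDX_RAD_2]
  tibia_fibula: [FXDX_TIB_1, FXDX_TIB_2]
  ankle: [FXDX_ANK_1, FXDX_ANK_2]
  clavicle: [FXDX_CLA_1, FXDX_CLA_2]

fracture_proc:
  hip: [FXPX_HIP_1]
  femur: [FXPX_FEM_1]
  pelvis: [FXPX_PEL_1]
  vertebral: [FXPX_VER_1]
  humerus: [FXPX_HUM_1]
  radius_ulna: [FXPX_RAD_1]
  tibia_fibula: [FXPX_TIB_1]
  ankle: [FXPX_ANK_1]
  clavicle: [FXPX_CLA_1]

em_proc: [EM_1, EM_2]

trauma_dx: [TRAUMA_1, TRAUMA_2]

op_dx: [OPDX_1, OPDX_2]

dxa_proc: [DXA_1]

ortho_surgery_proc: [SURG_1, SURG_2]

dme:
  walker: [DME_WALK_1]
  wheelchair: [DME_WC_1]
  other: [DME_OTH_1]

rehab: [REHAB_PT_1, REHAB_OT_1, REHAB_HH_1]

exclusion_dx:
  paget: [EXCL_PAGET_1]
  other_bone_disease: [EXCL_BONE_1]
  metabolic_bone_disease: [EXCL_METAB_1]
  cancer: [CANCER_1, CANCER_2, NMSC_1]

nonmelanoma_skin_cancer_dx: [NMSC_1]

cci:
  - {category: myocardial_infarction, weight: 1, codes: [CCI_MI_1]}
  - {category: congestive_heart_failure, weight: 1, codes: [CCI_CHF_1]}
  - {category: copd, weight: 1, codes: [CCI_COPD_1]}
  - {category: diabetes, weight: 1, codes: [CCI_DM_1]}
  - {category: renal_disease, weight: 2, codes: [CCI_RENAL_1]}
  - {category: any_malignancy, weight: 2, codes: [CCI_CA_1]}

comorbidity_dx:
  osteoarthritis: [COM_OA_1]
  rheumatoid_arthritis: [COM_RA_1]
  depression: [COM_DEP_1]
  anxiety: [COM_ANX_1]
  cardiovascular_disease: [COM_CVD_1]
  falls: [COM_FALL_1]
  smoking: [COM_SMOKE_1]

drug_class:
  teriparatide: [RX_TERI_1]
  abaloparatide: [RX_ABALO_1]
  romosozumab: [RX_ROMO_1]
  oral_BP: [RX_OBP_1, RX_OBP_2]
  IV_BP: [RX_IVBP_1]
  denosumab: [RX_DENO_1]
  SERM: [RX_SERM_1]
  calcitonin: [RX_CALC_1]
  corticosteroid: [RX_CORT_1]
  narcotic: [RX_NARC_1]
  antidepressant: [RX_ADEP_1]
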