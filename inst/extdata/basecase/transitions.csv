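"strategy","from","to","mean_p","lcl","ucl","alpha","beta","source_label"
"no_ert","asymptomatic","signs_symptoms",0.04,0.024,0.06,NA,NA,"synthetic_placeholder"
"no_ert","signs_symptoms","splenectomy",0.025,0.015,0.0375,NA,NA,"synthetic_placeholder"
"no_ert","signs_symptoms","bone_complication",0.02,0.012,0.03,NA,NA,"synthetic_placeholder"
"no_ert","signs_symptoms","malignancy",0.003,0.0018,0.0045,NA,NA,"synthetic_placeholder"
"no_ert","splenectomy","multiple_complications",0.04,0.024,0.06,NA,NA,"synthetic_placeholder"
"no_ert","splenectomy","malignancy",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"no_ert","bone_complication","multiple_complications",0.05,0.03,0.075,NA,NA,"synthetic_placeholder"
"no_ert","bone_complication","malignancy",0.005,0.003,0.0075,NA,NA,"synthetic_placeholder"
"no_ert","multiple_complications","malignancy",0.012,0.0072,0.018,NA,NA,"synthetic_placeholder"
"ert_base","asymptomatic","signs_symptoms",0.04,0.024,0.06,NA,NA,"synthetic_placeholder"
"ert_base","signs_symptoms","recovery",0.18,0.108,0.27,NA,NA,"synthetic_placeholder"
"ert_base","signs_symptoms","splenectomy",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"ert_base","signs_symptoms","bone_complication",0.01,0.006,0.015,NA,NA,"synthetic_placeholder"
"ert_base","signs_symptoms","malignancy",0.002,0.0012,0.003,NA,NA,"synthetic_placeholder"
"ert_base","recovery","splenectomy",0.004,0.0024,0.006,NA,NA,"synthetic_placeholder"
"ert_base","recovery","bone_complication",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"ert_base","recovery","malignancy",0.002,0.0012,0.003,NA,NA,"synthetic_placeholder"
"ert_base","splenectomy","multiple_complications",0.02,0.012,0.03,NA,NA,"synthetic_placeholder"
"ert_base","splenectomy","malignancy",0.005,0.003,0.0075,NA,NA,"synthetic_placeholder"
"ert_base","bone_complication","multiple_complications",0.025,0.015,0.0375,NA,NA,"synthetic_placeholder"
"ert_base","bone_complication","malignancy",0.004,0.0024,0.006,NA,NA,"synthetic_placeholder"
"ert_base","multiple_complications","malignancy",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"ert_historical","asymptomatic","signs_symptoms",0.04,0.024,0.06,NA,NA,"synthetic_placeholder"
"ert_historical","signs_symptoms","recovery",0.18,0.108,0.27,NA,NA,"synthetic_placeholder"
"ert_historical","signs_symptoms","splenectomy",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"ert_historical","signs_symptoms","bone_complication",0.01,0.006,0.015,NA,NA,"synthetic_placeholder"
"ert_historical","signs_symptoms","malignancy",0.002,0.0012,0.003,NA,NA,"synthetic_placeholder"
"ert_historical","recovery","splenectomy",0.004,0.0024,0.006,NA,NA,"synthetic_placeholder"
"ert_historical","recovery","bone_complication",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
"ert_historical","recovery","malignancy",0.002,0.0012,0.003,NA,NA,"synthetic_placeholder"
"ert_historical","splenectomy","multiple_complications",0.02,0.012,0.03,NA,NA,"synthetic_placeholder"
"ert_historical","splenectomy","malignancy",0.005,0.003,0.0075,NA,NA,"synthetic_placeholder"
"ert_historical","bone_complication","multiple_complications",0.025,0.015,0.0375,NA,NA,"synthetic_placeholder"
"ert_historical","bone_complication","malignancy",0.004,0.0024,0.006,NA,NA,"synthetic_placeholder"
"ert_historical","multiple_complications","malignancy",0.008,0.0048,0.012,NA,NA,"synthetic_placeholder"
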