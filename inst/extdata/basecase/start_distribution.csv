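"strategy","state","fraction"
"no_ert","asymptomatic",1
"ert_base","asymptomatic",1
"ert_historical","asymptomatic",1
"historical_I","signs_symptoms",0.35
"historical_I","splenectomy",0.25
"historical_I","bone_complication",0.2
"historical_I","multiple_complications",0.15
"historical_I","malignancy",0.05
"historical_II","signs_symptoms",0.2
"historical_II","splenectomy",0.25
"historical_II","bone_complication",0.2
"historical_II","multiple_complications",0.25
"historical_II","malignancy",0.1
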