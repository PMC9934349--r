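database,covariate,p_incident_2x,p_incident_1x,published_smd
CCAE,sle_diagnosis,0.87,0.48,0.64
CCAE,hydroxychloroquine,0.38,0.19,0.31
MDCD,sle_diagnosis,0.92,0.57,0.61
MDCD,hydroxychloroquine,0.27,0.15,0.21
MDCR,sle_diagnosis,0.83,0.49,0.54
MDCR,hydroxychloroquine,0.29,0.15,0.24
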