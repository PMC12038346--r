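{
  "name": "triple-network 24-ROI atlas",
  "description": "24 cortical regions of interest grouped into five network systems: visual (VN), auditory (AN), default mode (DMN), salience (SN) and central executive (CEN). Each bilateral region is expanded into a left (L_) and right (R_) ROI; ROI order is region order with left before right.",
  "rois": [
    {"roi": "L_V1",    "region": "Primary visual cortex",                "brodmann": "BA17", "abbrev": "V1",    "network": "VN",  "hemisphere": "L"},
    {"roi": "R_V1",    "region": "Primary visual cortex",                "brodmann": "BA17", "abbrev": "V1",    "network": "VN",  "hemisphere": "R"},
    {"roi": "L_V2",    "region": "Secondary visual cortex",              "brodmann": "BA18", "abbrev": "V2",    "network": "VN",  "hemisphere": "L"},
    {"roi": "R_V2",    "region": "Secondary visual cortex",              "brodmann": "BA18", "abbrev": "V2",    "network": "VN",  "hemisphere": "R"},
    {"roi": "L_A1",    "region": "Primary auditory cortex",              "brodmann": "BA41", "abbrev": "A1",    "network": "AN",  "hemisphere": "L"},
    {"roi": "R_A1",    "region": "Primary auditory cortex",              "brodmann": "BA41", "abbrev": "A1",    "network": "AN",  "hemisphere": "R"},
    {"roi": "L_A2",    "region": "Secondary auditory cortex",            "brodmann": "BA42", "abbrev": "A2",    "network": "AN",  "hemisphere": "L"},
    {"roi": "R_A2",    "region": "Secondary auditory cortex",            "brodmann": "BA42", "abbrev": "A2",    "network": "AN",  "hemisphere": "R"},
    {"roi": "L_PHC",   "region": "Parahippocampal gyrus",                "brodmann": "BA27", "abbrev": "PHC",   "network": "DMN", "hemisphere": "L"},
    {"roi": "R_PHC",   "region": "Parahippocampal gyrus",                "brodmann": "BA27", "abbrev": "PHC",   "network": "DMN", "hemisphere": "R"},
    {"roi": "L_PCC",   "region": "Posterior cingulate cortex",           "brodmann": "BA23", "abbrev": "PCC",   "network": "DMN", "hemisphere": "L"},
    {"roi": "R_PCC",   "region": "Posterior cingulate cortex",           "brodmann": "BA23", "abbrev": "PCC",   "network": "DMN", "hemisphere": "R"},
    {"roi": "L_AG",    "region": "Angular gyrus",                        "brodmann": "BA39", "abbrev": "AG",    "network": "DMN", "hemisphere": "L"},
    {"roi": "R_AG",    "region": "Angular gyrus",                        "brodmann": "BA39", "abbrev": "AG",    "network": "DMN", "hemisphere": "R"},
    {"roi": "L_MPFC",  "region": "Medial prefrontal cortex",             "brodmann": "BA46", "abbrev": "MPFC",  "network": "DMN", "hemisphere": "L"},
    {"roi": "R_MPFC",  "region": "Medial prefrontal cortex",             "brodmann": "BA46", "abbrev": "MPFC",  "network": "DMN", "hemisphere": "R"},
    {"roi": "L_INS",   "region": "Insula",                               "brodmann": "BA13", "abbrev": "INS",   "network": "SN",  "hemisphere": "L"},
    {"roi": "R_INS",   "region": "Insula",                               "brodmann": "BA13", "abbrev": "INS",   "network": "SN",  "hemisphere": "R"},
    {"roi": "L_dACC",  "region": "Dorsolateral anterior cingulate gyrus","brodmann": "BA24", "abbrev": "dACC",  "network": "SN",  "hemisphere": "L"},
    {"roi": "R_dACC",  "region": "Dorsolateral anterior cingulate gyrus","brodmann": "BA24", "abbrev": "dACC",  "network": "SN",  "hemisphere": "R"},
    {"roi": "L_DLPFC", "region": "Dorsolateral prefrontal cortex",       "brodmann": "BA09", "abbrev": "DLPFC", "network": "CEN", "hemisphere": "L"},
    {"roi": "R_DLPFC", "region": "Dorsolateral prefrontal cortex",       "brodmann": "BA09", "abbrev": "DLPFC", "network": "CEN", "hemisphere": "R"},
    {"roi": "L_PPC",   "region": "Posterior parietal cortex",            "brodmann": "BA40", "abbrev": "PPC",   "network": "CEN", "hemisphere": "L"},
    {"roi": "R_PPC",   "region": "Posterior parietal cortex",            "brodmann": "BA40", "abbrev": "PPC",   "network": "CEN", "hemisphere": "R"}
  ]
}
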