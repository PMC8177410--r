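[
  {"tag":"x1","name":"sex_rec","kind":"binary","source":"sex_rec","category":null,"note":"Recipient sex: male (1), female (0)"},
  {"tag":"x2","name":"age_rec","kind":"continuous","source":"age_rec","category":null,"note":"Recipient age at transplant (years)"},
  {"tag":"x3","name":"desease2_copd","kind":"dummy","source":"desease2","category":"COPD","note":"Recipient pathology: chronic obstructive pulmonary disease"},
  {"tag":"x4","name":"desease2_pf","kind":"dummy","source":"desease2","category":"PF","note":"Recipient pathology: pulmonary fibrosis"},
  {"tag":"x5","name":"desease2_bronchiectasis","kind":"dummy","source":"desease2","category":"bronchiectasis","note":"Recipient pathology: bronchiectasis"},
  {"tag":"x6","name":"desease2_cf","kind":"dummy","source":"desease2","category":"CF","note":"Recipient pathology: cystic fibrosis"},
  {"tag":"x7","name":"desease2_others","kind":"dummy","source":"desease2","category":"others","note":"Recipient pathology: other"},
  {"tag":"x8","name":"pre_tx_ambulatory","kind":"dummy","source":"pre_tx","category":"ambulatory","note":"Pre-transplant recipient status: ambulatory"},
  {"tag":"x9","name":"pre_tx_hospitalized","kind":"dummy","source":"pre_tx","category":"hospitalized","note":"Pre-transplant recipient status: hospitalized"},
  {"tag":"x10","name":"pre_tx_icu","kind":"dummy","source":"pre_tx","category":"ICU","note":"Pre-transplant recipient status: intensive care unit"},
  {"tag":"x11","name":"sex_donor","kind":"binary","source":"sex_donor","category":null,"note":"Donor sex: male (1), female (0)"},
  {"tag":"x12","name":"age_donor","kind":"continuous","source":"age_donor","category":null,"note":"Donor age (years)"},
  {"tag":"x13","name":"death_d_hs","kind":"dummy","source":"death_d","category":"HS","note":"Donor cause of death: hemorrhagic stroke"},
  {"tag":"x14","name":"death_d_tbi","kind":"dummy","source":"death_d","category":"TBI","note":"Donor cause of death: traumatic brain injury"},
  {"tag":"x15","name":"death_d_other","kind":"dummy","source":"death_d","category":"other","note":"Donor cause of death: other"},
  {"tag":"x16","name":"death_d_anoxia","kind":"dummy","source":"death_d","category":"ANOXIA","note":"Donor cause of death: anoxia"},
  {"tag":"x17","name":"death_d_is","kind":"dummy","source":"death_d","category":"IS","note":"Donor cause of death: ischemic stroke"},
  {"tag":"x18","name":"ti_in_do","kind":"continuous","source":"ti_in_do","category":null,"note":"Time with endotracheal intubation (days)"},
  {"tag":"x19","name":"io2_donor","kind":"continuous","source":"io2_donor","category":null,"note":"Donor oxygenation index: PaO2/FiO2"},
  {"tag":"x20","name":"type_tx_singleft","kind":"dummy","source":"type_tx","category":"singleft","note":"Transplant type: single left lung"},
  {"tag":"x21","name":"type_tx_singright","kind":"dummy","source":"type_tx","category":"singright","note":"Transplant type: single right lung"},
  {"tag":"x22","name":"type_tx_bilateral","kind":"dummy","source":"type_tx","category":"bilateral","note":"Transplant type: bilateral"},
  {"tag":"x23","name":"type_tx_bilobular","kind":"dummy","source":"type_tx","category":"bilobular cadaver","note":"Transplant type: bilobular cadaver"},
  {"tag":"x24","name":"type_tx_ho_bipulm","kind":"dummy","source":"type_tx","category":"Ho+Bipulm","note":"Transplant type: Ho+Bipulm"},
  {"tag":"x25","name":"cold_isch_long","kind":"dummy","source":"cold_isch","category":"Long","note":"Cold ischemia time 4 to 6 hours"},
  {"tag":"x26","name":"cold_isch_medium","kind":"dummy","source":"cold_isch","category":"Medium","note":"Cold ischemia time 2 to 4 hours"},
  {"tag":"x27","name":"cold_isch_verylong","kind":"dummy","source":"cold_isch","category":"Very long","note":"Cold ischemia time over 6 hours"},
  {"tag":"x28","name":"cold_isch_short","kind":"dummy","source":"cold_isch","category":"Short","note":"Cold ischemia time 0 to 2 hours"},
  {"tag":"x29","name":"bypass","kind":"binary","source":"bypass","category":null,"note":"Cardiopulmonary bypass applied: 1 (YES), 0 (NO)"},
  {"tag":"x30","name":"tailor","kind":"binary","source":"Tailor","category":null,"note":"Pulmonary tailoring: 1 (YES), 0 (NO)"},
  {"tag":"x31","name":"po2_pre","kind":"continuous","source":"po2_pre","category":null,"note":"Pre-transplant oxygen pressure PO2 (mmHg)"},
  {"tag":"x32","name":"pco2_pre","kind":"continuous","source":"pco2_pre","category":null,"note":"Pre-transplant carbon dioxide pressure PCO2 (mmHg)"},
  {"tag":"x33","name":"fvc_pre","kind":"continuous","source":"fvc_pre","category":null,"note":"Pre-transplant functional vital capacity FVC (% predicted)"},
  {"tag":"x34","name":"fvc_prp","kind":"continuous","source":"fvc_prp","category":null,"note":"Post-transplant functional vital capacity FVC (% predicted)"},
  {"tag":"x35","name":"fev1_pre","kind":"continuous","source":"fev1_pre","category":null,"note":"Pre-transplant forced expiratory volume FEV1 (% predicted)"},
  {"tag":"x36","name":"fev1_prp","kind":"continuous","source":"fev1_prp","category":null,"note":"Post-transplant forced expiratory volume FEV1 (% predicted)"}
]
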