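parameter,value,note
horizon_years,6,projection horizon (calendar years)
start_year,2024,first calendar year
new_diagnoses,50000,SYNTHETIC PLACEHOLDER - annual new surveillance entrants (England-scale magnitude; not a registry value)
survival,0.95,SYNTHETIC PLACEHOLDER - annual survival probability
attrition,0.05,SYNTHETIC PLACEHOLDER - annual probability of leaving surveillance
p_conservation,0.8,fraction with breast-conserving surgery
unit_cost,115.25,mammogram unit cost (GBP 2023)
savings_start_year,4,years since diagnosis at which reduced surveillance begins
window_years,8,total years in surveillance
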