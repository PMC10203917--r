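from,to
SEQN,id
SDMVSTRA,stratum
SDMVPSU,psu
WTMEC2YR,weight
RIDAGEYR,age
RIAGENDR,sex
RIDRETH1,race_ethnicity
DMDEDUC2,education
DMDMARTL,marital
INDFMPIR,income_poverty_ratio
SLD010H,sleep_hours
BMXHT,height_cm
BMXWT,weight_kg
BPXSY1,sbp_1
BPXSY2,sbp_2
BPXSY3,sbp_3
BPXDI1,dbp_1
BPXDI2,dbp_2
BPXDI3,dbp_3
LBXGLU,fasting_glucose_mgdl
LBXGH,hba1c_pct
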