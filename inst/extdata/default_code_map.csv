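condition,class,pattern,prefix
nvaf,nvaf,427.31,FALSE
nvaf,nvaf,I48,TRUE
valvular_disease,valvular,394,TRUE
valvular_disease,valvular,396,TRUE
valvular_disease,valvular,I05,TRUE
valvular_disease,valvular,I08,TRUE
valvular_disease,valvular,V43.3,FALSE
valvular_disease,valvular,Z95.2,FALSE
vte,vte,415.1,TRUE
vte,vte,453.4,TRUE
vte,vte,I26,TRUE
vte,vte,I82.4,TRUE
heart_failure,stroke_risk,428,TRUE
heart_failure,stroke_risk,I50,TRUE
hypertension,stroke_risk,401,TRUE
hypertension,stroke_risk,I10,FALSE
diabetes,stroke_risk,250,TRUE
diabetes,stroke_risk,E11,TRUE
stroke,stroke_risk,434,TRUE
stroke,stroke_risk,435,TRUE
stroke,stroke_risk,I63,TRUE
stroke,stroke_risk,G45,TRUE
vascular_disease,stroke_risk,440,TRUE
vascular_disease,stroke_risk,I70,TRUE
vascular_disease,stroke_risk,443.9,FALSE
prior_bleeding,stroke_risk,578,TRUE
prior_bleeding,stroke_risk,K92.2,FALSE
prior_bleeding,stroke_risk,430,FALSE
prior_bleeding,stroke_risk,I62,TRUE
elix_copd,elixhauser,496,TRUE
elix_copd,elixhauser,J44,TRUE
elix_liver_disease,elixhauser,571,TRUE
elix_liver_disease,elixhauser,K76,TRUE
elix_renal_failure,elixhauser,585,TRUE
elix_renal_failure,elixhauser,N18,TRUE
elix_hypothyroidism,elixhauser,244,TRUE
elix_hypothyroidism,elixhauser,E03,TRUE
elix_anemia,elixhauser,285,TRUE
elix_anemia,elixhauser,D64,TRUE
elix_depression,elixhauser,311,TRUE
elix_depression,elixhauser,F32,TRUE
elix_cancer,elixhauser,199,TRUE
elix_cancer,elixhauser,C80,TRUE
elix_obesity,elixhauser,278.0,FALSE
elix_obesity,elixhauser,E66,TRUE
elix_arthritis,elixhauser,714,TRUE
elix_arthritis,elixhauser,M05,TRUE
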