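job_id,question_id,response
J01,met_welding,yes
J01,met_iron,yes
J01,met_lead,no
J01,pm_dusty_env,yes
J01,pm_dust_freq,often
J01,pm_src_weld_fume,yes
J01,comb_diesel_exhaust,no
J02,met_other,yes
J02,met_welding,no
J02,pm_dusty_env,yes
J02,voc_solvent_use,yes
J03,pm_dusty_env,no
J03,voc_solvent_use,no
J03,met_lead,no
J04,bio_animals,no
J04,pm_dusty_env,no
J05,comb_diesel_exhaust,yes
J05,comb_truck_bay,yes
J05,comb_freq,sometimes
J05,pm_dusty_env,yes
J06,bio_lab_agents,yes
J06,rad_xray,yes
J06,corr_acid,no
J07,pm_dusty_env,no
J08,pest_apply,yes
J08,pest_mix,yes
J08,pest_freq,often
J08,bio_animals,yes
J10,pm_dusty_env,no
J10,voc_solvent_use,no
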