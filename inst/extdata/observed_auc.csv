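compound,species,dose_ug_kg,infusion_h,auc_obs_ng_h_ml
MTM,mouse,2000,0,1906
MTM,rat,500,0,173
MTM,monkey,6.94,0.1667,90
MTM,monkey,13.18,0.1667,255
MTM,human,13,6,136
MTMSA-Trp,mouse,2000,0,38563
MTMSA-Trp,rat,500,0,3486
MTMSA-Trp,monkey,1.34,0.1667,139
MTMSA-Trp,monkey,4.19,0.1667,181
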