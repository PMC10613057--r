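service_id,kind,quantity,cadre,unit_cost,per_episode
malaria_uncomplicated,drug,1,,0.9,
malaria_uncomplicated,diagnostic,1,,0.5,
malaria_uncomplicated,human_resource,15,nurse,0.12,
anc_visit,human_resource,20,nurse,0.12,
anc_visit,reagent,2,,0.8,
anc_visit,diagnostic,1,,1.2,TRUE
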