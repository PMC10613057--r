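service_id,khis_group,levels_offered,encounters_per_episode,need_basis,need_rate
malaria_uncomplicated,outpatient_general,"dispensary,health_center,primary_hospital",1.5,incidence,0.25
anc_visit,maternal_health,"health_center,primary_hospital",4,utilization_rate,0.035
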