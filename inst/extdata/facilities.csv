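facility_id,sub_county,level,clinical_staff,nonclinical_staff,outpatient_visits,inpatient_bed_days,clinical_labor,drugs,medical_supplies,indirect
garb_disp_01,Garbatulla,dispensary,3,2,4542,0,20573,13528,0,4451
garb_hc_01,Garbatulla,health_center,21,5,11247,277,78341,32713,20,14736
garb_hosp_01,Garbatulla,primary_hospital,21,22,9620,666,302853,98987,0,96833
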