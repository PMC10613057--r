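sub_county,level,universe_op
Garbatulla,dispensary,8800
Garbatulla,health_center,11247
Garbatulla,primary_hospital,9620
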