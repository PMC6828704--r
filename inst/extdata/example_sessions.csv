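session_id,date,duration_hours,individuals_present
S1,2015-07-01,2.0,red;yellow;blue
S2,2015-07-28,2.5,red;yellow;blue
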