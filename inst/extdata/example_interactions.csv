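session_id,order_index,initiator_id,recipient_id,behaviour_code,outcome
S1,1,red,yellow,peck,initiator_wins
S1,2,yellow,blue,allopreen,not_applicable
S1,3,red,blue,displace,initiator_wins
S1,4,blue,red,jab,recipient_wins
S1,5,blue,yellow,chase,draw
S2,1,red,yellow,peck,initiator_wins
S2,2,yellow,blue,displace,initiator_wins
S2,3,red,yellow,allopreen,not_applicable
S2,4,yellow,red,approach,not_applicable
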