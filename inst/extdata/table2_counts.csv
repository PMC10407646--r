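stratum,group,self_harm,n
LOW,NEITHER,1,6792
LOW,NEITHER,0,3065664
LOW,TBI_ONLY,1,215
LOW,TBI_ONLY,0,25409
LOW,PTSD_ONLY,1,3407
LOW,PTSD_ONLY,0,209468
LOW,COMORBID,1,330
LOW,COMORBID,0,16330
MEDIUM,NEITHER,1,9466
MEDIUM,NEITHER,0,1377527
MEDIUM,TBI_ONLY,1,558
MEDIUM,TBI_ONLY,0,22851
MEDIUM,PTSD_ONLY,1,7548
MEDIUM,PTSD_ONLY,0,234050
MEDIUM,COMORBID,1,1342
MEDIUM,COMORBID,0,26252
HIGH,NEITHER,1,21979
HIGH,NEITHER,0,1123012
HIGH,TBI_ONLY,1,2335
HIGH,TBI_ONLY,0,42498
HIGH,PTSD_ONLY,1,25894
HIGH,PTSD_ONLY,0,412053
HIGH,COMORBID,1,6778
HIGH,COMORBID,0,51517
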