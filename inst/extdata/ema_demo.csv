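user_id,timestamp,q1,q2,q3,q4,q5,q6,q7
u01,2014-04-10T08:30:00,Y,62,55,40,58,45,70
u01,2014-04-10T14:10:00,Y,70,60,,62,50,
u01,2014-04-11T09:05:00,N,35,30,55,40,35,60
u01,2014-04-14T19:45:00,Y,80,75,30,72,68,40
u02,2014-04-12T10:00:00,N,20,15,70,25,20,80
u02,2014-04-13T11:30:00,,,,,,, 
u03,2014-05-01T07:55:00,Y,90,85,20,88,80,30
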