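user_id,tf1,tf2,tf3,tf4,tf5,tf6,tf7,tf8,tf9,tf10,tf11,tf12,minitf_score,sex,ageAtRegistration,ageAtOnset,onsetrelation,familyHistory,variability
u01,2,1,0,2,2,1,1,2,0,0,1,2,14,1,52,40,3,1,2
u02,0,0,1,0,0,1,0,0,0,0,0,0,2,2,31,29,4,2,1
u03,1,2,2,1,2,2,2,2,1,1,,2,,2,67,55,1,1,4
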