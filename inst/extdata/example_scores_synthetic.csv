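id,sex,age,group,brain_age
EC001,female,4.6,CTR,3.1
EC002,female,5.8,CTR,4.9
EC003,female,4.2,CTR,2.4
EC004,female,6.5,CTR,5.3
EC005,female,5.1,CTR,3.6
EC006,male,4.9,CTR,5.4
EC007,male,6.8,CTR,7.1
EC008,male,4.4,CTR,5.6
EC009,male,5.5,CTR,6.9
EC010,male,6.1,CTR,6.5
EC011,male,4.7,CTR,4.1
EC012,male,5.9,CTR,7.0
EM001,female,4.4,MNR,5.9
EM002,female,4.2,MNR,5.5
EM003,female,4.6,MNR,5.3
EM004,female,4.3,MNR,6.1
EM005,female,4.5,MNR,5.2
EM006,male,5.2,MNR,6.3
EM007,male,6.9,MNR,7.4
EM008,male,4.1,MNR,3.3
EM009,male,5.7,MNR,8.9
EM010,male,6.3,MNR,5.8
EM011,male,4.8,MNR,5.0
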