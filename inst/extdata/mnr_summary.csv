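variable,unit,sex,group,n,mean,sd
birth_weight,kg,female,CTR,5,0.87,0.12
birth_weight,kg,female,MNR,5,0.78,0.15
birth_weight,kg,male,CTR,7,0.90,0.10
birth_weight,kg,male,MNR,6,0.83,0.09
weight_at_scan,kg,female,CTR,5,12.72,1.53
weight_at_scan,kg,female,MNR,5,13.90,0.98
weight_at_scan,kg,male,CTR,7,17.91,5.56
weight_at_scan,kg,male,MNR,6,20.77,4.65
age,years,female,CTR,5,4.75,0.76
age,years,female,MNR,5,4.38,0.20
age,years,male,CTR,7,5.00,1.34
age,years,male,MNR,6,5.55,1.38
gm_abs,ml,female,CTR,5,90.1,6.9
gm_abs,ml,female,MNR,5,86.4,4.4
gm_abs,ml,male,CTR,7,96.0,10.1
gm_abs,ml,male,MNR,6,99.0,13.2
wm_abs,ml,female,CTR,5,55.6,8.1
wm_abs,ml,female,MNR,5,53.2,4.6
wm_abs,ml,male,CTR,7,65.1,5.6
wm_abs,ml,male,MNR,6,65.1,8.6
csf_abs,ml,female,CTR,5,35.0,2.0
csf_abs,ml,female,MNR,5,41.8,4.4
csf_abs,ml,male,CTR,7,46.5,5.9
csf_abs,ml,male,MNR,6,41.8,3.0
tiv,ml,female,CTR,5,181.3,14.6
tiv,ml,female,MNR,5,195.4,21.5
tiv,ml,male,CTR,7,213.7,14.3
tiv,ml,male,MNR,6,206.7,22.4
gm_frac,per_tiv,female,CTR,5,0.50,0.01
gm_frac,per_tiv,female,MNR,5,0.48,0.01
gm_frac,per_tiv,male,CTR,7,0.47,0.01
gm_frac,per_tiv,male,MNR,6,0.48,0.02
wm_frac,per_tiv,female,CTR,5,0.31,0.02
wm_frac,per_tiv,female,MNR,5,0.29,0.01
wm_frac,per_tiv,male,CTR,7,0.31,0.02
wm_frac,per_tiv,male,MNR,6,0.32,0.01
csf_frac,per_tiv,female,CTR,5,0.19,0.02
csf_frac,per_tiv,female,MNR,5,0.23,0.02
csf_frac,per_tiv,male,CTR,7,0.22,0.02
csf_frac,per_tiv,male,MNR,6,0.20,0.02
brainage_score,years,female,CTR,5,-1.58,1.36
brainage_score,years,female,MNR,5,1.16,0.80
brainage_score,years,male,CTR,7,0.86,1.54
brainage_score,years,male,MNR,6,0.89,2.43
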