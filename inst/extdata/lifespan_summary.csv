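variable,unit,sex,n,mean,sd
age,years,female,15,9.43,3.89
age,years,male,14,9.62,6.02
gm_abs,ml,female,15,87.3,8.6
gm_abs,ml,male,14,95.9,8.8
wm_abs,ml,female,15,60.5,7.0
wm_abs,ml,male,14,67.4,5.3
csf_abs,ml,female,15,38.4,4.9
csf_abs,ml,male,14,46.5,5.1
tiv,ml,female,15,186.7,14.4
tiv,ml,male,14,210.4,14.0
gm_frac,per_tiv,female,15,0.47,0.03
gm_frac,per_tiv,male,14,0.46,0.02
wm_frac,per_tiv,female,15,0.32,0.02
wm_frac,per_tiv,male,14,0.32,0.02
csf_frac,per_tiv,female,15,0.21,0.02
csf_frac,per_tiv,male,14,0.22,0.02
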