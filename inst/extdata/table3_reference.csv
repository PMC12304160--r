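no,parameter,kind,param_id,observed_mean,observed_median,observed_sd,predicted_mean,predicted_median,predicted_sd
1,Right vermillion length,length,D23,19.8,19.7,1.99,19.6,19.7,2.11
2,Left vermillion length,length,D24,19.8,20.1,2.22,19.3,19.3,1.73
3,Right lateral volumetric vermillion length,surface_curve,S31,18.4,18.5,1.93,18.8,18.4,2.34
4,Left lateral volumetric vermillion length,surface_curve,S32,18.1,17.7,2.25,17.9,17.8,1.69
5,Right lateral columella length,length,D12,5.5,5.3,1.13,5.4,5.3,1.17
6,Left lateral columella length,length,D13,5.5,5.6,1.11,5.3,4.9,1.16
7,Effective nasal length,length,D4,8.3,8.4,0.90,8.0,8.4,1.13
8,Right volumetric lateral columella length,surface_curve,S8,6.9,6.4,1.85,7.2,7.1,1.59
9,Left volumetric lateral columella length,surface_curve,S9,6.7,6.6,1.52,6.7,6.4,1.72
10,Median sagittal columella length,length,D14,5.6,5.6,1.03,5.8,5.7,0.80
11,Philtrum length,length,D22,11.4,11.1,1.26,11.1,10.8,0.84
12,Right volumetric vermillion length,surface_curve,S25,22.5,22.9,2.16,22.9,23.3,2.33
13,Left volumetric vermillion length,surface_curve,S26,22.4,22.5,2.50,22.8,22.5,2.68
14,Transverse lengths of the right lateral lip element,length,D25,17.6,17.8,1.82,17.9,18.0,1.44
15,Transverse lengths of the left lateral lip element,length,D26,17.3,17.1,2.06,17.3,17.1,1.68
16,Volumetric philtrum length,surface_curve,S13,11.7,11.4,1.37,11.4,11.1,1.04
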