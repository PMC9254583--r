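code,naocl_pct,h2o2_pct,hgcl2_pct,time_min,de_actual,nde_actual,de_pred,nde_pred,de_resid,nde_resid
T0,0,0,0,20,0.00,,2.62,,-2.62,
T1,0.54,0,0,10,44.44,0.00,73.69,-17.96,-29.25,17.96
T2,0.54,0,0,20,27.78,0.00,26.80,6.94,0.97,-6.94
T3,0.54,0,0,30,55.56,0.00,29.24,20.12,26.32,-20.12
T4,0.90,0,0,10,72.22,0.00,68.95,-11.25,3.27,11.25
T5,0.90,0,0,20,72.22,7.69,59.76,-11.52,12.46,19.21
T6,0.90,0,0,30,50.00,0.00,44.14,8.05,5.86,-8.05
T7,1.26,0,0,10,44.44,0.00,46.57,5.19,-2.12,-5.19
T8,1.26,0,0,20,72.22,0.00,72.78,5.92,-0.55,-5.92
T9,1.26,0,0,30,77.78,14.29,77.27,9.96,0.51,4.33
T10,0,5.25,0,10,86.67,0.00,88.09,-2.67,-1.43,2.67
T11,0,5.25,0,20,83.33,6.67,87.28,19.88,-3.94,-13.22
T12,0,5.25,0,30,83.33,46.67,79.80,42.93,3.54,3.74
T13,0,8.75,0,10,77.78,28.57,74.38,18.49,3.40,10.08
T14,0,8.75,0,20,95.24,20.00,93.13,23.28,2.10,-3.28
T15,0,8.75,0,30,72.22,46.15,73.24,45.34,-1.02,0.82
T16,0,12.25,0,10,66.67,8.33,68.70,15.01,-2.03,-6.68
T17,0,12.25,0,20,100.00,11.11,94.02,12.39,5.98,-1.28
T18,0,12.25,0,30,89.47,23.53,88.80,18.68,0.67,4.85
T19,0,0,0.05,5,100.00,38.89,105.35,32.30,-5.35,6.59
T20,0,0,0.05,10,100.00,44.44,98.48,42.27,1.52,2.18
T21,0,0,0.05,15,100.00,35.29,94.90,52.14,5.10,-16.84
T22,0,0,0.10,5,100.00,22.22,96.30,48.45,3.70,-26.23
T23,0,0,0.10,10,100.00,100.00,92.63,60.53,1.48,39.47
T24,0,0,0.10,15,100.00,52.94,104.76,64.75,-4.76,-11.81
T25,0,0,0.20,5,100.00,83.33,83.73,78.71,16.27,4.63
T26,0,0,0.20,10,100.00,100.00,105.48,80.24,-5.48,19.76
T27,0,0,0.20,15,100.00,88.24,134.70,76.73,-34.70,11.51
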