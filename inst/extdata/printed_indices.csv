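code,context,rwc,eli
Co,prescreen,78.2,1.78
Qm,prescreen,76.8,2.94
Qg,prescreen,72.9,2.68
Aj,prescreen,35.6,8.00
Qa,drought,NA,0.75
Qp,drought,NA,0.75
Qs,drought,NA,0.71
Tj,drought,NA,1.38
Aj,drought,NA,10.0
Qa,dual_stress,NA,1.75
Qp,dual_stress,NA,3.13
Qs,dual_stress,NA,3.06
Tj,dual_stress,NA,2.63
Aj,dual_stress,NA,32.5
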