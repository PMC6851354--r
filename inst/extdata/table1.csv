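patient_id,stage,modality,sites,affected_rate,nonaffected_rate,seizure_freq,ilae
P1,pre,scalp,C4;O2;P4;T6,4.01,3.48,30,NA
P2,pre,scalp,C3;F7;T3;T5,7.03,0.45,180,NA
P3,pre,scalp,F4;F8;T4;T6,0.26,0.39,0.5,NA
P4,pre,scalp,F4;F8;T4;T6,0.48,0.17,2,NA
P5,pre,scalp,C3;F3;Fp1,1.68,0.34,8,NA
P6,pre,scalp,C4;F8;T6,0.63,0.16,12,NA
P7,pre,scalp,F7;C3;T3;T5,0.62,0.02,4,NA
P8,pre,scalp,C4;F4;F8;Fp2,11.18,2.72,450,NA
P1,post,scalp,C4;O2;P4;T6,0.43,0.18,0.2,3
P2,post,scalp,C3;F7;T3;T5,3.57,0.85,180,5
P2,post,scalp,C3;F7;T3;T5,0.52,0.18,0,1
P3,post,scalp,F4;F8;T4;T6,0.23,0.21,1,3
P4,post,scalp,C4;F4;F8;T4,2.36,2.21,15,5
P5,post,scalp,C3;F3;F7;Fp1,0.10,0.04,0,1
P6,post,scalp,C4;F8;T4;T6,0.25,0.21,0,1
P7,post,scalp,C3;F7;T3;T5,0.15,0.10,0,1
P9,post,scalp,C4;F4;F8;Fp2,0.53,0.37,0,1
P10,post,scalp,C4;F4;F8;Fp2,0.63,0.44,0.35,NA
P11,post,scalp,O2;P4;T4;T6,0.08,0.07,0,1
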