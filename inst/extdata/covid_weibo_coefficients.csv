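model,emotion,b_intercept,b_emotion,b_severity,b_interaction,r2,f
1,happiness,-0.02,-0.09,0.26,-0.27,0.12,1.66
2,anger,0.13,0.45,0.79,0.77,0.28,4.74
3,sadness,0.13,-0.12,0.70,-0.57,0.25,4.21
4,fear,-0.04,-0.26,0.24,0.14,0.19,2.94
5,disgust,0.03,-0.01,0.42,0.36,0.13,1.85
6,surprise,0.17,-0.11,0.91,-0.62,0.33,6.21
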