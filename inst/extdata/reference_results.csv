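sb_stenosis_pct,alpha_deg,sb_flow_pct,dp_mb,ffr_mb,dp_sb,ffr_sb
40,40,25,14.89,0.851,7.10,0.929
40,55,25,14.93,0.851,8.37,0.916
40,70,25,14.71,0.853,9.26,0.907
40,40,35,13.07,0.869,7.36,0.926
40,55,35,12.82,0.872,8.69,0.913
40,70,35,12.58,0.874,9.54,0.905
40,40,45,11.55,0.885,7.80,0.922
40,55,45,11.12,0.889,9.19,0.908
40,70,45,10.93,0.891,10.04,0.900
60,40,25,14.85,0.851,9.35,0.906
60,55,25,15.20,0.848,10.99,0.890
60,70,25,15.41,0.846,12.80,0.872
60,40,35,13.26,0.867,11.09,0.889
60,55,35,13.31,0.867,13.34,0.867
60,70,35,13.51,0.865,15.18,0.848
60,40,45,12.06,0.881,13.81,0.862
60,55,45,11.89,0.881,16.73,0.833
60,70,45,12.12,0.879,18.58,0.814
80,40,25,15.20,0.848,22.53,0.775
80,55,25,15.27,0.847,30.54,0.695
80,70,25,15.63,0.844,36.03,0.640
80,40,35,13.76,0.862,35.50,0.645
80,55,35,13.55,0.864,49.61,0.504
80,70,35,13.87,0.861,57.72,0.423
80,40,45,12.69,0.873,52.66,0.473
80,55,45,12.30,0.877,74.16,0.258
80,70,45,12.60,0.874,85.98,0.140
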