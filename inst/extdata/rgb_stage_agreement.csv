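video_id,duration,rr_ref,rr_video_total,abs_err_total,rel_err_total,rr_video_r1,abs_err_r1,rel_err_r1,rr_video_r2,abs_err_r2,rel_err_r2,rr_video_r3,abs_err_r3,rel_err_r3
1,00:26,32.31,32.05,0.26,0.80,32.10,0.21,0.64,31.75,0.56,1.73,27.96,4.35,13.46
2,00:26,33.17,31.65,1.52,4.59,31.59,1.58,4.77,31.76,1.41,4.26,31.72,1.45,4.38
3,00:26,30.00,29.69,0.31,1.03,29.72,0.28,0.93,28.04,1.96,6.53,29.60,0.40,1.33
4,06:03,20.04,21.10,1.06,5.28,22.02,1.98,9.87,20.49,0.45,2.24,23.12,3.08,15.36
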