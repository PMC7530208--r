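sample_id,mlss_g_per_L,r_mean,g_mean,b_mean,n_pixels,n_replicates,in_reference_fit
S01,0,232.08,232.09,233.6,NA,3,TRUE
S02,0.263,229.51,229.35,229.71,NA,3,TRUE
S03,0.34,225.81,225.51,225.66,NA,3,TRUE
S04,0.527,225.85,224.62,223.85,NA,3,TRUE
S05,0.644,225.58,224.5,223.7,NA,3,TRUE
S06,0.772,225.4,224.41,223.49,NA,3,TRUE
S07,0.966,225.03,224.11,223.001,NA,3,TRUE
S08,1.053,224.97,223.36,221.49,NA,3,TRUE
S09,1.931,224.46,222.18,216.78,NA,3,TRUE
S10,2.318,224.26,220.21,210.13,NA,3,TRUE
S11,2.897,221.07,212.37,193.21,NA,3,TRUE
S12,5.795,212.44,190.33,138.33,NA,3,TRUE
S13,6.623,211.21,188.84,138.42,NA,3,TRUE
S14,6.439,207.118,184.67,136.23,NA,3,TRUE
S15,6.954,200.72,176.9,122.58,NA,3,TRUE
S16,7.243,200.35,174.85,123.05,NA,3,TRUE
S17,7.726,197.4,170.91,118.35,NA,3,TRUE
S18,8.585,190.2,157.97,102.74,NA,3,TRUE
S19,11.59,174.36,130.76,66.12,NA,3,TRUE
S20,12.33,174.56,131.07,67.7,NA,3,TRUE
S21,12.98,165.33,121.65,53.14,NA,3,FALSE
S22,13.52,142.19,101.2,34.193,NA,3,FALSE
S23,14.901,128.15,81.26,26.2,NA,3,TRUE
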