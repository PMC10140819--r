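study_id,route,parameter,observed,predicted,printed_ratio
iv_1988_155,iv,Cmax,1716.74,1457.96,1.17
iv_1988_155,iv,AUC0_t,6587.57,5405.63,1.21
iv_1988_155,iv,CL,16.9,20.6,0.82
iv_1988_310,iv,Cmax,2321.71,2017.4,1.15
iv_1988_310,iv,AUC0_t,12607.25,11122.39,1.13
iv_1988_310,iv,CL,12,20.36,0.6
iv_1989_155,iv,Cmax,2105.9,1517.82,1.38
iv_1989_155,iv,AUC0_t,8649.54,5553.82,1.55
iv_1989_155,iv,CL,10.2,20.27,0.51
iv_1992_155,iv,Cmax,1287.03,1280.82,1
iv_1992_155,iv,AUC0_t,3984.54,3364.52,1.18
iv_1992_155,iv,CL,31.05,26.85,1.15
oral_1988_v1w1,oral,Cmax,249.18,251.96,0.98
oral_1988_v1w1,oral,AUC0_t,5812.48,6566.34,0.88
oral_1988_v1w1,oral,CL,38.94,37.98,1.02
oral_1988_v1w4,oral,Cmax,311.932,236.80,1.31
oral_1988_v1w4,oral,AUC0_t,17952.57,9209.71,1.94
oral_1988_v1w4,oral,CL,10.06,25.59,0.5
oral_1988_v2w1,oral,Cmax,261.05,264.16,0.98
oral_1988_v2w1,oral,AUC0_t,8237.36,9667.94,0.85
oral_1988_v2w1,oral,CL,28.78,24.59,1.17
oral_1988_v2w4,oral,Cmax,311.932,236.80,1.31
oral_1988_v2w4,oral,AUC0_t,17938.45,9210.98,1.94
oral_1988_v2w4,oral,CL,10.12,25.51,0.5
oral_1989_155,oral,Cmax,180.77,197.96,0.91
oral_1989_155,oral,AUC0_t,5470.81,4596.05,1.19
oral_1989_155,oral,CL,21.56,24.05,0.89
oral_1992_155,oral,Cmax,183.5,214.80,0.85
oral_1992_155,oral,AUC0_t,2432.33,3680.55,0.66
oral_1992_155,oral,CL,52.32,28.29,1.84
oral_1995_200,oral,Cmax,117.427,226.99,0.51
oral_1995_200,oral,AUC0_t,988.14,1799.07,0.54
oral_1995_200,oral,CL,110.03,76.76,1.43
oral_2012_200,oral,Cmax,171.833,288.66,0.59
oral_2012_200,oral,AUC0_t,2446.55,3771.88,0.64
oral_2012_200,oral,CL,61.33,38.94,1.57
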