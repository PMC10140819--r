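stage,route,median_auc0_t,ci95_low,ci95_high
healthy,iv,5317,5142,5532
CP-A,iv,7096,6465,7528
CP-B,iv,8176,7772,8650
CP-C,iv,9204,8645,9709
CKD-moderate,iv,5187,4904,5519
CKD-severe,iv,5088,4665,5466
healthy,oral,4989,4812,5245
CP-A,oral,6966,6488,7600
CP-B,oral,7961,7171,8600
CP-C,oral,8735,8449,9632
CKD-moderate,oral,4890,4539,5235
CKD-severe,oral,4961,4603,5342
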